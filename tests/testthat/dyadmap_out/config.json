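{"pairs":null,"genome":null,"depth":null,"out_dir":"dyadmap_out","dialect":"pairs","read_size":"auto","min_dist":160,"lambda_bp":75,"gamma1":80,"gamma2":-2,"window":1000,"overlap":200,"max_iter":50,"b_clip":3,"occupancy_w":30,"flank":500,"seed":1,"stages":"nonsense","hash":"      NA"}
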