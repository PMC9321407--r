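# Tetra-nucleosome folding motifs. Four consecutive nucleosomes fold either
# as an alpha-tetrahedron (contact-dense neighborhood) or a beta-rhombus
# (contact-sparse). Per-nucleosome 10-dim features are the upper triangle
# (diagonal included) of the 4x4 contact submatrix over nucleosomes
# i-1..i+2; features are grouped by neighborhood contact sum, a binary
# classifier is selected per group by held-out F1, and regional motif
# preference is quantified by an odds-ratio against the genome-wide
# composition.

# fixed row-major upper-triangle order of the 4x4 submatrix
.TETRA_IDX <- cbind(r = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L),
                    c = c(1L, 2L, 3L, 4L, 2L, 3L, 4L, 3L, 4L, 4L))

#' Extract 10-dimensional tetra-nucleosome contact features
#'
#' For every eligible nucleosome i (needing neighbors i-1 and i+2 on the
#' same chromosome), extracts the upper triangle including the diagonal of
#' the symmetric 4x4 contact-count submatrix over nucleosomes i-1..i+2, in
#' row-major order. Boundary nucleosomes are skipped.
#'
#' @param map A `nuc_contact_map`.
#' @param value Edge column used as matrix entries (`"count"` default,
#'   `"oe"` after [oe_normalize()]).
#' @return `data.table` of class `tetra_features`: `chrom`, `node`, `f1`..
#'   `f10`, `contact_sum`, `group`; attribute `n_skipped` counts boundary
#'   skips.
#' @export
extract_features <- function(map, value = "count") {
  nodes <- map$nodes
  out <- list()
  n_skipped <- 0L
  for (ch in unique(nodes$chrom)) {
    nd <- nodes$node[nodes$chrom == ch]
    n <- length(nd)
    n_skipped <- n_skipped + min(n, 3L)   # i=1, i=n-1, i=n lack neighbors
    if (n < 4L) next
    e <- map$edges[map$edges$chrom == ch, ]
    lo <- min(nd)
    nrel <- n
    M <- Matrix::sparseMatrix(i = e$node_i - lo + 1L,
                              j = e$node_j - lo + 1L,
                              x = as.numeric(e[[value]]),
                              dims = c(nrel, nrel), symmetric = TRUE)
    ctr <- 2:(n - 2L)                    # eligible relative indices
    f <- matrix(0, length(ctr), 10L)
    for (q in seq_len(10L)) {
      ri <- ctr - 2L + .TETRA_IDX[q, "r"]
      ci <- ctr - 2L + .TETRA_IDX[q, "c"]
      f[, q] <- M[cbind(ri, ci)]
    }
    dt <- data.table::as.data.table(f)
    data.table::setnames(dt, sprintf("f%d", 1:10))
    data.table::set(dt, NULL, "chrom", ch)
    data.table::set(dt, NULL, "node", nd[ctr])
    data.table::set(dt, NULL, "contact_sum", rowSums(f))
    out[[ch]] <- dt
  }
  res <- if (length(out)) data.table::rbindlist(out) else
    data.table::data.table()
  res <- group_features(res)
  attr(res, "n_skipped") <- n_skipped
  data.table::setattr(res, "class",
                      c("tetra_features", class(res)))
  res
}

#' Group tetra features by neighborhood contact sum
#'
#' Left-inclusive bins on the feature sum: group 1 below 200 contacts,
#' group 2 in `[200, 400)`, group 3 in `[400, 600)`, group 4 at 600 and
#' above. Group 1 neighborhoods are too sparse for reliable prediction and
#' are always labelled `unpredicted` downstream.
#'
#' @param features Tetra feature table with a `contact_sum` column.
#' @param breaks Group boundaries.
#' @return The table with an integer `group` column.
#' @export
group_features <- function(features, breaks = c(200, 400, 600)) {
  if (nrow(features) == 0L) {
    data.table::set(features, NULL, "group", integer(0))
    return(features)
  }
  g <- findInterval(features$contact_sum, breaks) + 1L
  data.table::set(features, NULL, "group", g)
  features
}

.f1_score <- function(truth, pred, positive = "alpha") {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  if (tp == 0) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

#' Default classifier set for folding-motif prediction
#'
#' Ten standard binary-classification families: k-nearest neighbors (k=3),
#' linear SVM (C=0.025), RBF SVM (gamma=2, C=1), Gaussian-process
#' classifier (RBF), depth-5 decision tree, small random forest (10 trees),
#' multilayer perceptron, boosted trees, Gaussian naive Bayes, and
#' quadratic discriminant analysis. Each entry is a list with `fit(x, y)`
#' and `predict(model, x)`; the set is pluggable — pass any named list of
#' such entries to [train_select()].
#'
#' @return Named list of classifier definitions.
#' @export
default_classifiers <- function() {
  list(
    knn = list(
      fit = function(x, y) list(x = x, y = y),
      predict = function(m, x) as.character(
        class::knn(m$x, x, m$y, k = 3))),
    svm_linear = list(
      fit = function(x, y) e1071::svm(x, y, kernel = "linear", cost = 0.025),
      predict = function(m, x) as.character(stats::predict(m, x))),
    svm_rbf = list(
      fit = function(x, y) e1071::svm(x, y, kernel = "radial", gamma = 2,
                                      cost = 1),
      predict = function(m, x) as.character(stats::predict(m, x))),
    gauss_process = list(
      fit = function(x, y) kernlab::gausspr(x, y, kernel = "rbfdot"),
      predict = function(m, x) as.character(kernlab::predict(m, x))),
    decision_tree = list(
      fit = function(x, y) {
        d <- data.frame(x, y = y)
        rpart::rpart(y ~ ., d, method = "class",
                     control = rpart::rpart.control(maxdepth = 5))
      },
      predict = function(m, x) as.character(
        stats::predict(m, data.frame(x), type = "class"))),
    random_forest = list(
      fit = function(x, y) randomForest::randomForest(x, y, ntree = 10,
                                                      maxnodes = 32),
      predict = function(m, x) as.character(stats::predict(m, x))),
    mlp = list(
      fit = function(x, y) nnet::nnet(x, nnet::class.ind(y), size = 8,
                                      decay = 1, maxit = 1000,
                                      softmax = TRUE, trace = FALSE),
      predict = function(m, x) {
        p <- stats::predict(m, x)
        colnames(p)[max.col(p, ties.method = "first")]
      }),
    boosted_trees = list(
      fit = function(x, y) {
        lev <- levels(y)
        m <- xgboost::xgboost(data = as.matrix(x),
                              label = as.integer(y) - 1L,
                              nrounds = 20, max_depth = 3,
                              objective = "binary:logistic", verbose = 0,
                              nthread = 1)
        list(model = m, lev = lev)
      },
      predict = function(m, x) {
        p <- stats::predict(m$model, as.matrix(x))
        m$lev[as.integer(p > 0.5) + 1L]
      }),
    naive_bayes = list(
      fit = function(x, y) e1071::naiveBayes(x, y),
      predict = function(m, x) as.character(
        stats::predict(m, x))),
    qda = list(
      fit = function(x, y) MASS::qda(x, y),
      predict = function(m, x) as.character(
        stats::predict(m, x)$class))
  )
}

#' Train and select a folding-motif classifier per contact group
#'
#' Within each of groups 2-4, randomly splits the labelled nucleosomes into
#' 75% training and 25% test, fits every classifier in the set, scores
#' held-out F1 (alpha as the positive class), and keeps the best. Group 1
#' is never trained: its nucleosomes stay `unpredicted`. Groups with a
#' single label class are skipped with a warning. Classifier failures score
#' `NA` and are ignored in selection.
#'
#' @param features A `tetra_features` table.
#' @param labels Factor/character vector of `alpha`/`beta` labels aligned
#'   with `features` rows.
#' @param split_fraction Training fraction.
#' @param classifiers Named classifier list ([default_classifiers()]).
#' @param seed Integer seed controlling the split.
#' @return Object of class `tetra_models`: `models` (per group), `report`
#'   (`data.table` group x classifier F1), `selected` (named character).
#' @export
train_select <- function(features, labels, split_fraction = 0.75,
                         classifiers = default_classifiers(), seed = 1L) {
  stopifnot(nrow(features) == length(labels))
  labels <- factor(as.character(labels), levels = c("alpha", "beta"))
  fcols <- sprintf("f%d", 1:10)
  set.seed(seed)
  models <- list()
  report <- list()
  selected <- character()
  for (g in 2:4) {
    idx <- which(features$group == g & !is.na(labels))
    if (length(idx) < 8L) next
    y <- droplevels(labels[idx])
    if (nlevels(y) < 2L) {
      warning(sprintf("group %d has a single label class; skipped", g))
      next
    }
    x <- as.matrix(features[idx, fcols, with = FALSE])
    n_tr <- max(2L, floor(split_fraction * length(idx)))
    tr <- sample.int(length(idx), n_tr)
    te <- setdiff(seq_along(idx), tr)
    if (!length(te)) next
    f1s <- vapply(names(classifiers), function(nm) {
      cl <- classifiers[[nm]]
      tryCatch({
        m <- cl$fit(x[tr, , drop = FALSE], factor(y[tr], levels = levels(y)))
        pr <- cl$predict(m, x[te, , drop = FALSE])
        .f1_score(as.character(y[te]), pr)
      }, error = function(e) NA_real_)
    }, numeric(1))
    if (all(is.na(f1s))) next
    best <- names(f1s)[which.max(f1s)]
    cl <- classifiers[[best]]
    models[[as.character(g)]] <- list(
      name = best,
      fit = cl$fit(x, y),       # refit on the full group for deployment
      predict = cl$predict,
      f1 = max(f1s, na.rm = TRUE))
    selected[as.character(g)] <- best
    report[[length(report) + 1L]] <- data.table::data.table(
      group = g, classifier = names(f1s), f1 = unname(f1s))
  }
  structure(list(models = models,
                 report = if (length(report))
                   data.table::rbindlist(report) else data.table::data.table(),
                 selected = selected),
            class = "tetra_models")
}

#' Predict folding-motif labels
#'
#' Applies each group's selected classifier to its features. Group 1 (and
#' any group without a model) is labelled `unpredicted`.
#'
#' @param features A `tetra_features` table.
#' @param trained A `tetra_models` object from [train_select()].
#' @return Factor with levels `alpha`, `beta`, `unpredicted`, one per
#'   feature row.
#' @export
predict_motifs <- function(features, trained) {
  out <- rep("unpredicted", nrow(features))
  fcols <- sprintf("f%d", 1:10)
  for (g in names(trained$models)) {
    idx <- which(features$group == as.integer(g))
    if (!length(idx)) next
    m <- trained$models[[g]]
    x <- as.matrix(features[idx, fcols, with = FALSE])
    out[idx] <- m$predict(m$fit, x)
  }
  factor(out, levels = c("alpha", "beta", "unpredicted"))
}

.motif_counts <- function(labels) {
  labels <- as.character(labels)
  c(alpha = as.numeric(sum(labels == "alpha")),
    beta = as.numeric(sum(labels == "beta")))
}

#' Folding-motif ratio of a region against the genome
#'
#' The odds ratio `(n_local(alpha) * n_genome(beta)) /
#' (n_local(beta) * n_genome(alpha))`. Values above 1 indicate a regional
#' preference towards the alpha-tetrahedron, below 1 towards the
#' beta-rhombus.
#'
#' @param local Labels (factor/character) of nucleosomes in the region.
#' @param genome Genome-wide labels.
#' @return List of class `folding_ratio`: the four counts and `ratio`.
#' @export
folding_ratio <- function(local, genome) {
  nl <- .motif_counts(local)
  ng <- .motif_counts(genome)
  if (any(c(nl, ng) == 0)) {
    stop("all four alpha/beta counts must be positive")
  }
  structure(list(n_local = nl, n_genome = ng,
                 ratio = unname((nl["alpha"] * ng["beta"]) /
                                  (nl["beta"] * ng["alpha"]))),
            class = "folding_ratio")
}

#' @method print folding_ratio
#' @export
print.folding_ratio <- function(x, ...) {
  cat(sprintf("folding ratio %.3f (local %d/%d alpha/beta vs genome %d/%d)\n",
              x$ratio, x$n_local["alpha"], x$n_local["beta"],
              x$n_genome["alpha"], x$n_genome["beta"]))
  invisible(x)
}

#' Resampling significance of a folding-motif ratio
#'
#' Draws `n_resamples` random genome subsets of the region's size, computes
#' each subset's log folding ratio against the genome, and scores the
#' observed log-ratio as a new observation from that null distribution:
#' `t = (observed - mean(resamples)) / sd(resamples)`, two-sided p from the
#' t distribution with `n_resamples - 1` degrees of freedom. Degenerate
#' resamples (a zero class count) are redrawn up to a capped number of
#' retries.
#'
#' @inheritParams folding_ratio
#' @param n_resamples Number of genome subsets.
#' @param seed Integer seed.
#' @param max_retries Redraw cap per degenerate resample.
#' @return List: `p_value`, `observed_log_ratio`, `resampled_log_ratios`.
#' @export
ratio_significance <- function(local, genome, n_resamples = 1000L, seed = 1L,
                               max_retries = 100L) {
  local <- as.character(local); genome <- as.character(genome)
  local <- local[local %in% c("alpha", "beta")]
  genome <- genome[genome %in% c("alpha", "beta")]
  n_local <- length(local)
  if (n_local < 20L) stop("need at least 20 labelled local nucleosomes")
  obs <- log(folding_ratio(local, genome)$ratio)
  set.seed(seed)
  lr <- vapply(seq_len(n_resamples), function(b) {
    for (t in seq_len(max_retries)) {
      sub <- genome[sample.int(length(genome), n_local)]
      cnt <- .motif_counts(sub)
      if (all(cnt > 0)) return(log(folding_ratio(sub, genome)$ratio))
    }
    stop("degenerate resamples: a label class is near-absent genome-wide")
  }, numeric(1))
  tstat <- (obs - mean(lr)) / stats::sd(lr)
  list(p_value = 2 * stats::pt(-abs(tstat), df = n_resamples - 1L),
       observed_log_ratio = unname(obs),
       t = unname(tstat),
       resampled_log_ratios = lr)
}
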