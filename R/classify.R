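#' SVM kernel specification
#'
#' Fixes the kernel family and its hyper-parameters for the
#' leave-one-out experiments. Defaults follow the study configuration:
#' cost C = 1 for every kernel; polynomial of order 3; RBF with sigma 1
#' under the parameterization k(x, y) = exp(-||x - y||^2 / (2 sigma^2))
#' (set `rbf_form = "plain"` for exp(-||x - y||^2 / sigma^2)); sigmoid
#' tanh(gamma <x, y> + coef0). Where gamma is left `NULL` it defaults to
#' 1 / (feature dimension) at fit time, the libsvm convention.
#'
#' @param kind `"linear"`, `"polynomial"`, `"rbf"` or `"sigmoid"`.
#' @param C soft-margin cost (default 1).
#' @param degree polynomial degree (default 3).
#' @param sigma RBF width (default 1).
#' @param rbf_form `"halved"` (2 sigma^2 denominator) or `"plain"`.
#' @param gamma,coef0 secondary parameters for the polynomial and
#'   sigmoid kernels; `gamma = NULL` means 1/dimension, `coef0` defaults
#'   to 1 (polynomial) or 0 (sigmoid).
#' @return a list of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("linear", "polynomial", "rbf", "sigmoid"),
                        C = 1, degree = 3, sigma = 1,
                        rbf_form = c("halved", "plain"),
                        gamma = NULL, coef0 = NULL) {
  kind <- match.arg(kind)
  rbf_form <- match.arg(rbf_form)
  if (is.null(coef0)) coef0 <- if (kind == "polynomial") 1 else 0
  structure(list(kind = kind, C = C, degree = degree, sigma = sigma,
                 rbf_form = rbf_form, gamma = gamma, coef0 = coef0),
            class = "kernel_spec")
}

# Resolve a kernel_spec to e1071::svm arguments for dimension d.
svm_args <- function(ks, d) {
  gamma <- ks$gamma
  if (ks$kind == "rbf") {
    gamma <- if (ks$rbf_form == "halved") 1 / (2 * ks$sigma^2) else 1 / ks$sigma^2
  } else if (is.null(gamma)) {
    gamma <- 1 / d
  }
  list(kernel = switch(ks$kind, linear = "linear",
                       polynomial = "polynomial", rbf = "radial",
                       sigmoid = "sigmoid"),
       cost = ks$C, degree = ks$degree, gamma = gamma, coef0 = ks$coef0)
}

# Feature matrix for one region set: 13 columns for a single region, 39
# (region-major: posterior, middle, anterior) for "all". Rows are
# subjects; returns x, y (factor labels) and subject ids.
region_matrix <- function(table, region_set) {
  check_cohort_table(table)
  regions <- c("posterior", "middle", "anterior")
  stopifnot(region_set %in% c(regions, "all"))
  use <- if (region_set == "all") regions else region_set
  subjects <- unique(table$subject)
  fcols <- paste0("f", 1:13)
  blocks <- lapply(use, function(reg) {
    sub <- table[table$region == reg, ]
    if (!setequal(sub$subject, subjects))
      stop("region ", reg, " does not cover every subject")
    m <- as.matrix(sub[match(subjects, sub$subject), fcols])
    colnames(m) <- paste0(reg, "_", fcols)
    m
  })
  x <- do.call(cbind, blocks)
  rownames(x) <- subjects
  y <- factor(table$label[match(subjects, table$subject)],
              levels = c("nonsparse", "sparse"))
  list(x = x, y = y, subjects = subjects)
}

#' Leave-one-out SVM accuracy for one region set and kernel
#'
#' Each subject is predicted by an SVM trained on all remaining
#' subjects. Features are standardized (zero mean, unit variance) using
#' the training fold's statistics only, so no information about the
#' held-out subject enters the model. Accuracy is the fraction of
#' correct held-out predictions over all subjects. A training fold that
#' loses one class entirely cannot be fit; such folds are counted as
#' errors with a warning.
#'
#' @param table cohort feature table (see [cohort_features()]).
#' @param region_set `"posterior"`, `"middle"`, `"anterior"` or `"all"`
#'   (all three regions concatenated, 39 features).
#' @param kernel a [kernel_spec()].
#' @return an `rgf_cv` object: region set, kernel, per-fold `predicted`
#'   and `truth`, `accuracy`, `n_correct`, `n_total`.
#' @export
loocv_accuracy <- function(table, region_set = "middle",
                           kernel = kernel_spec("linear")) {
  stopifnot(inherits(kernel, "kernel_spec"))
  rm <- region_matrix(table, region_set)
  n <- nrow(rm$x)
  if (min(table(rm$y)) < 2L)
    stop("need at least two subjects per class")
  args <- svm_args(kernel, ncol(rm$x))
  pred <- factor(rep(NA_character_, n), levels = levels(rm$y))
  for (i in seq_len(n)) {
    xtr <- rm$x[-i, , drop = FALSE]
    ytr <- rm$y[-i]
    if (nlevels(droplevels(ytr)) < 2L) {
      warning("training fold ", i, " lost a class; counted as an error")
      next
    }
    mu <- colMeans(xtr)
    sg <- apply(xtr, 2, stats::sd)
    sg[sg == 0 | !is.finite(sg)] <- 1
    xtr <- sweep(sweep(xtr, 2, mu), 2, sg, "/")
    xte <- (rm$x[i, ] - mu) / sg
    fit <- e1071::svm(x = xtr, y = ytr, type = "C-classification",
                      kernel = args$kernel, cost = args$cost,
                      degree = args$degree, gamma = args$gamma,
                      coef0 = args$coef0, scale = FALSE)
    pred[i] <- stats::predict(fit, matrix(xte, nrow = 1))
  }
  correct <- sum(pred == rm$y, na.rm = TRUE)
  structure(list(region_set = region_set, kernel = kernel,
                 subjects = rm$subjects, predicted = pred, truth = rm$y,
                 accuracy = correct / n, n_correct = correct, n_total = n),
            class = "rgf_cv")
}

#' @export
print.rgf_cv <- function(x, ...) {
  cat(sprintf("<rgf_cv> %s region set, %s kernel: LOO accuracy %.3f (%d/%d)\n",
              x$region_set, x$kernel$kind, x$accuracy, x$n_correct,
              x$n_total))
  invisible(x)
}

#' Run the full kernel-by-region classification experiment
#'
#' Evaluates leave-one-out accuracy for every combination of the four
#' kernels (linear, polynomial, RBF, sigmoid) and the four region sets
#' (posterior, middle, anterior, all combined), 16 cells in a fixed
#' order.
#'
#' @param table cohort feature table.
#' @param kernels list of [kernel_spec()]s (default the four standard
#'   ones).
#' @param region_sets character vector of region sets.
#' @return an `rgf_experiment`: `results` (data.frame with `region_set`,
#'   `kernel`, `accuracy`, `n_correct`, `n_total`) and `folds` (the
#'   underlying `rgf_cv` objects).
#' @export
run_experiment <- function(table,
                           kernels = lapply(c("linear", "polynomial",
                                              "rbf", "sigmoid"),
                                            kernel_spec),
                           region_sets = c("posterior", "middle",
                                           "anterior", "all")) {
  folds <- list()
  rows <- list()
  for (rs in region_sets) {
    for (ks in kernels) {
      cv <- loocv_accuracy(table, rs, ks)
      folds[[paste(rs, ks$kind, sep = ".")]] <- cv
      rows[[length(rows) + 1L]] <- data.frame(
        region_set = rs, kernel = ks$kind, accuracy = cv$accuracy,
        n_correct = cv$n_correct, n_total = cv$n_total)
    }
  }
  structure(list(results = do.call(rbind, rows), folds = folds),
            class = "rgf_experiment")
}

#' @export
print.rgf_experiment <- function(x, ...) {
  cat("<rgf_experiment> leave-one-out accuracy\n")
  tab <- stats::xtabs(accuracy ~ region_set + kernel, data = x$results)
  tab <- round(unclass(tab), 3)
  attr(tab, "call") <- NULL
  print(tab)
  invisible(x)
}
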