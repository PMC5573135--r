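#' Category structures for the categorization task
#'
#' Builds the four-category bivariate-normal structure used throughout the
#' package. Two structures are available: the rule-based (`"RB"`) structure,
#' whose four categories share a diagonal covariance and differ only on the
#' second (orientation-like) dimension, so that three horizontal criteria
#' separate them; and the information-integration (`"II"`) structure, whose
#' category means lie on a diagonal in stimulus space and whose shared
#' covariance is correlated, so that the optimal bounds require integrating
#' both dimensions.
#'
#' Coordinates are abstract stimulus-space units (dim1 is bar-width-like,
#' dim2 is orientation-like); no conversion to physical units is attempted.
#'
#' @param kind `"RB"` or `"II"`.
#' @param categories Optional list of four category definitions overriding
#'   the built-in parameters. Each element must be a list with fields
#'   `label` (one of A--D, unique), `mean` (numeric 2-vector) and `cov`
#'   (2x2 symmetric positive-definite matrix).
#'
#' @return An object of class `category_structure`: a list with fields
#'   `kind` and `categories` (named list A--D of `label`/`mean`/`cov`).
#' @export
#' @examples
#' rb <- category_structure("RB")
#' sapply(rb$categories, function(ct) ct$mean[2])
category_structure <- function(kind = c("RB", "II"), categories = NULL) {
  if (!is.character(kind) || length(kind) != 1L || !kind %in% c("RB", "II")) {
    stop("`kind` must be \"RB\" or \"II\".", call. = FALSE)
  }
  if (is.null(categories)) {
    categories <- if (kind == "RB") {
      sigma <- matrix(c(0.44, 0, 0, 0.01), 2, 2)
      list(
        list(label = "A", mean = c(1.9, 0.30), cov = sigma),
        list(label = "B", mean = c(1.9, 0.67), cov = sigma),
        list(label = "C", mean = c(1.9, 1.03), cov = sigma),
        list(label = "D", mean = c(1.9, 1.40), cov = sigma)
      )
    } else {
      sigma <- matrix(c(0.06, 0.04, 0.04, 0.06), 2, 2)
      list(
        list(label = "A", mean = c(0.92, 2.49), cov = sigma),
        list(label = "B", mean = c(1.50, 1.93), cov = sigma),
        list(label = "C", mean = c(2.02, 1.41), cov = sigma),
        list(label = "D", mean = c(2.59, 0.82), cov = sigma)
      )
    }
  }
  structure_obj <- structure(
    list(kind = kind, categories = categories),
    class = "category_structure"
  )
  names(structure_obj$categories) <-
    vapply(structure_obj$categories, function(ct) ct$label, character(1))
  validate_category_structure(structure_obj)
  structure_obj
}

cat_labels <- c("A", "B", "C", "D")

validate_category_structure <- function(x) {
  stopifnot(inherits(x, "category_structure"))
  labels <- unname(vapply(x$categories, function(ct) ct$label, character(1)))
  if (length(labels) != 4L || !identical(sort(labels), cat_labels) ||
      anyDuplicated(labels) > 0L) {
    stop("a category structure needs exactly four categories labeled A-D.",
         call. = FALSE)
  }
  for (ct in x$categories) {
    if (length(ct$mean) != 2L || !is.numeric(ct$mean)) {
      stop("category means must be numeric 2-vectors.", call. = FALSE)
    }
    cv <- ct$cov
    if (!is.matrix(cv) || !all(dim(cv) == 2L) ||
        max(abs(cv - t(cv))) > 1e-12 || any(eigen(cv, symmetric = TRUE,
                                                  only.values = TRUE)$values <= 0)) {
      stop("category covariances must be 2x2 symmetric positive-definite.",
           call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.category_structure <- function(x, ...) {
  cat("<category_structure> kind:", x$kind, "\n")
  for (ct in x$categories) {
    cat(sprintf("  %s: mean = (%.3f, %.3f), cov = [%.3f %.3f; %.3f %.3f]\n",
                ct$label, ct$mean[1], ct$mean[2],
                ct$cov[1, 1], ct$cov[1, 2], ct$cov[2, 1], ct$cov[2, 2]))
  }
  invisible(x)
}

#' Axis used by the decision-bound model and bound-based observers
#'
#' The bounds are one-dimensional, so stimuli are projected onto a fixed
#' unit axis along which the four category means are ordered A < B < C < D:
#' pure dim2 for the RB structure and the diagonal `(1, -1)/sqrt(2)` for the
#' II structure.
#'
#' @param kind `"RB"` or `"II"` (or a `category_structure`).
#' @return A unit-norm numeric 2-vector.
#' @export
projection_axis <- function(kind) {
  if (inherits(kind, "category_structure")) kind <- kind$kind
  switch(kind,
    RB = c(0, 1),
    II = c(1, -1) / sqrt(2),
    stop("`kind` must be \"RB\" or \"II\".", call. = FALSE)
  )
}

#' Moment-match a sample to target mean and covariance
#'
#' Linearly transforms a finite 2-D sample so that its sample mean and
#' sample covariance (unbiased, denominator n-1) exactly equal the targets:
#' `y_i = target_mean + T (x_i - xbar)` with `T = L_t L_s^{-1}`, where `L_t`
#' and `L_s` are lower-triangular Cholesky factors of the target and sample
#' covariances. This is the "randomization technique" used to build the
#' stimulus sets: every generated set has exactly the generative moments.
#'
#' @param points Numeric matrix or data frame with two columns (n >= 4 rows).
#' @param target_mean Numeric 2-vector.
#' @param target_cov 2x2 symmetric positive-definite matrix.
#' @return A numeric matrix of the same dimensions as `points`.
#' @export
#' @examples
#' x <- matrix(rnorm(40), ncol = 2)
#' y <- moment_match(x, c(0, 0), diag(2))
#' colMeans(y)  # exactly (0, 0)
moment_match <- function(points, target_mean, target_cov) {
  x <- as.matrix(points)
  if (ncol(x) != 2L) stop("`points` must have two columns.", call. = FALSE)
  if (nrow(x) < 4L) {
    stop("moment matching needs at least 4 points.", call. = FALSE)
  }
  s <- stats::cov(x)
  ls <- tryCatch(t(chol(s)), error = function(e) NULL)
  if (is.null(ls) || any(diag(ls) < 1e-12)) {
    stop("degenerate sample: sample covariance is singular.", call. = FALSE)
  }
  lt <- t(chol(target_cov))
  tr <- lt %*% solve(ls)
  centered <- sweep(x, 2, colMeans(x))
  y <- centered %*% t(tr)
  y <- sweep(y, 2, target_mean, `+`)
  dimnames(y) <- dimnames(x)
  y
}

#' Draw a moment-matched stimulus sample
#'
#' Draws per-category samples from the structure's bivariate normals, then
#' moment-matches each category so its sample mean and covariance equal the
#' generative parameters exactly, and finally shuffles the pooled set. The
#' default counts (125, 175, 175, 125) yield the 600-stimulus set the
#' session protocol consumes: 125 training stimuli per category plus 50 B
#' and 50 C stimuli reserved for the transfer test.
#'
#' @param structure A `category_structure`.
#' @param counts Named or positional integer vector of per-category counts
#'   (A, B, C, D), each >= 4.
#' @param seed Integer seed; the same seed reproduces the sample exactly.
#' @return A data frame with columns `dim1`, `dim2`, `category`.
#' @export
sample_stimuli <- function(structure,
                           counts = c(A = 125, B = 175, C = 175, D = 125),
                           seed = 1L) {
  validate_category_structure(structure)
  counts <- as.integer(counts)
  if (length(counts) != 4L || any(is.na(counts)) || any(counts < 4L)) {
    stop("`counts` must be four integers, each >= 4.", call. = FALSE)
  }
  names(counts) <- cat_labels
  withr::with_seed(seed, {
    per_cat <- lapply(cat_labels, function(lab) {
      ct <- structure$categories[[lab]]
      x <- MASS::mvrnorm(counts[[lab]], mu = ct$mean, Sigma = ct$cov)
      y <- moment_match(x, ct$mean, ct$cov)
      data.frame(dim1 = y[, 1], dim2 = y[, 2], category = lab,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, per_cat)
    out <- out[sample.int(nrow(out)), , drop = FALSE]
  })
  rownames(out) <- NULL
  out
}

#' Read or write a stimulus sample as CSV
#'
#' Plain CSV with header `dim1,dim2,category`, decimal point, UTF-8, LF.
#' Coordinates are written with 17 significant digits so that a round trip
#' is numerically exact.
#'
#' @param stimuli Data frame with columns `dim1`, `dim2`, `category`.
#' @param path File path.
#' @return `read_stimuli_csv` returns the data frame; `write_stimuli_csv`
#'   returns `path` invisibly.
#' @export
write_stimuli_csv <- function(stimuli, path) {
  stopifnot(all(c("dim1", "dim2", "category") %in% names(stimuli)))
  out <- data.frame(
    dim1 = sprintf("%.17g", stimuli$dim1),
    dim2 = sprintf("%.17g", stimuli$dim2),
    category = stimuli$category,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_stimuli_csv
#' @export
read_stimuli_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!identical(names(df), c("dim1", "dim2", "category"))) {
    stop("stimulus CSV must have header dim1,dim2,category.", call. = FALSE)
  }
  df$dim1 <- as.numeric(df$dim1)
  df$dim2 <- as.numeric(df$dim2)
  df
}
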