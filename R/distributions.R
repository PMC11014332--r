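#' Class distribution of a label vector
#'
#' Tallies labels over a taxonomy's full class list (zero-count classes are
#' kept). `NA` labels — seconds that were unlabeled in the raw log — are
#' excluded, mirroring their exclusion from training data.
#'
#' @param labels Character vector of class names (may contain `NA`).
#' @param tax A [taxonomy_map()], or a character vector of class names.
#' @return A list of class `class_distribution` with integer `counts` (named
#'   by class) and `total`.
#' @export
#' @examples
#' class_distribution(c("sedentary", "sedentary", "active"),
#'                    taxonomy_map("T1_sedentary"))
class_distribution <- function(labels, tax) {
  classes <- if (inherits(tax, "taxonomy_map")) tax$classes else tax
  labels <- labels[!is.na(labels)]
  bad <- setdiff(unique(labels), classes)
  if (length(bad) > 0) {
    stop("label(s) outside the class set: ", paste(bad, collapse = ", "))
  }
  counts <- table(factor(labels, levels = classes))
  new_class_distribution(setNames(as.integer(counts), classes))
}

new_class_distribution <- function(counts) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  structure(list(counts = counts, total = sum(counts)),
            class = "class_distribution")
}

#' @export
print.class_distribution <- function(x, ...) {
  cat("<class_distribution> total =", x$total, "\n")
  print(x$counts)
  invisible(x)
}

as_proportions <- function(d) {
  counts <- if (inherits(d, "class_distribution")) d$counts else d
  total <- sum(counts)
  if (total <= 0) stop("distribution has zero total")
  counts / total
}

#' Chi-square distance between two class distributions
#'
#' Histogram chi-square dissimilarity on normalized proportions,
#' `D(p, q) = 1/2 * sum_i (p_i - q_i)^2 / (p_i + q_i)` over classes with
#' `p_i + q_i > 0`. Symmetric, zero iff the proportions are equal, and equal
#' to 1 for disjoint one-hot distributions. The asymmetric Pearson
#' goodness-of-fit form `sum (p_i - q_i)^2 / q_i` (reference `q`) is available
#' as an alternative.
#'
#' @param p,q `class_distribution` objects or named nonnegative vectors on the
#'   same class set. Normalized to proportions internally.
#' @param method `"histogram"` (default) or `"pearson"`.
#' @return Nonnegative scalar distance.
#' @export
#' @examples
#' t1 <- taxonomy_map("T1_sedentary")
#' p <- class_distribution(rep(c("sedentary", "active"), c(7, 3)), t1)
#' q <- class_distribution(rep(c("sedentary", "active"), c(5, 5)), t1)
#' chi2_distance(p, q)
chi2_distance <- function(p, q, method = c("histogram", "pearson")) {
  method <- match.arg(method)
  pp <- as_proportions(p)
  qq <- as_proportions(q)
  if (!identical(sort(names(pp)), sort(names(qq)))) {
    stop("distributions are over different class sets")
  }
  qq <- qq[names(pp)]
  if (method == "histogram") {
    s <- pp + qq
    keep <- s > 0
    0.5 * sum((pp[keep] - qq[keep])^2 / s[keep])
  } else {
    keep <- qq > 0
    sum((pp[keep] - qq[keep])^2 / qq[keep])
  }
}
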