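# One-way permutational multivariate analysis of variance (PERMANOVA) on
# Euclidean distances, used to compare per-sample summary metrics (sum_tq,
# sum_ear, sum_ear_med, concentrations) between supply groups.

#' Pairwise Euclidean distance matrix
#'
#' @param points numeric matrix or data.frame, one row per observation.
#'   One-dimensional input may be a plain vector.
#' @return symmetric N x N matrix of Euclidean distances, zero diagonal.
#' @export
euclidean_distances <- function(points) {
  if (is.vector(points) && !is.list(points)) points <- matrix(points, ncol = 1)
  points <- as.matrix(points)
  if (!all(is.finite(points)))
    stop("points must be finite (no NA/NaN/Inf)")
  as.matrix(dist(points, method = "euclidean"))
}

# Within-group sum of squares from a squared-distance matrix:
# sum over groups of (1/n_g) * sum_{i<j in g} d_ij^2.
.ss_within <- function(d2, groups) {
  ss <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1)
      ss <- ss + sum(d2[idx, idx]) / 2 / length(idx)
  }
  ss
}

.pseudo_f <- function(ss_among, ss_within, a, n) {
  if (ss_within == 0) {
    if (ss_among == 0) return(NaN)
    return(Inf)
  }
  (ss_among / (a - 1)) / (ss_within / (n - a))
}

# All distinct orderings of a label multiset, as a list of character vectors.
# Feasible only for small N (used by the exact-enumeration mode and tests).
.multiset_permutations <- function(labels) {
  uniq <- unique(labels)
  if (length(labels) == 1) return(list(labels))
  out <- list()
  for (u in uniq) {
    rest <- labels[-match(u, labels)]
    for (tail in .multiset_permutations(rest))
      out[[length(out) + 1L]] <- c(u, tail)
  }
  out
}

#' One-way PERMANOVA
#'
#' Distance-based one-way permutational MANOVA.  Sums of squares follow the
#' standard decomposition on squared inter-point distances:
#' SS_total = (1/N) sum_{i<j} d_ij^2, SS_within = sum_g (1/n_g)
#' sum_{i<j in g} d_ij^2, SS_among = SS_total - SS_within, and the
#' pseudo-F is (SS_among/(a-1)) / (SS_within/(N-a)).  The p-value uses
#' add-one smoothing, p = (1 + #{permuted F >= observed F}) / (1 + m), with
#' the observed labeling entering only through the +1 terms, so p > 0
#' always.  With `exact = TRUE` all distinct label orderings are enumerated
#' instead and p is the exact fraction with F >= observed (feasible N <~ 10).
#'
#' Degenerate inputs are defined rather than fatal: all points identical
#' gives SS_total = 0, F = NaN, p = 1; perfectly separated groups give
#' F = +Inf with p still from permutation counts.
#'
#' @param dist_matrix N x N symmetric distance matrix (see
#'   [euclidean_distances()]); a `dist` object is also accepted.
#' @param groups length-N vector of group labels; at least two groups.
#' @param n_permutations number of random permutations (default 9999).
#' @param seed integer seed for the permutation stream.
#' @param exact logical; enumerate all distinct labelings instead of
#'   sampling.
#' @return list of class `permanova_result`: `f_stat`, `p_value`,
#'   `n_permutations`, `group_sizes`, `ss_total`, `ss_among`, `ss_within`,
#'   `seed`, `exact`.
#' @export
permanova_oneway <- function(dist_matrix, groups, n_permutations = 9999,
                             seed = 1, exact = FALSE) {
  if (inherits(dist_matrix, "dist")) dist_matrix <- as.matrix(dist_matrix)
  groups <- as.character(groups)
  n <- length(groups)
  stopifnot(nrow(dist_matrix) == n, ncol(dist_matrix) == n, n >= 3)
  a <- length(unique(groups))
  if (a < 2) stop("at least two groups are required")

  d2 <- dist_matrix^2
  ss_total <- sum(d2) / 2 / n
  ss_within <- .ss_within(d2, groups)
  ss_among <- ss_total - ss_within
  f_obs <- .pseudo_f(ss_among, ss_within, a, n)
  sizes <- as.integer(table(groups))

  if (ss_total <= .Machine$double.eps * n) {
    res <- list(f_stat = NaN, p_value = 1, n_permutations = 0L,
                group_sizes = sizes, ss_total = 0, ss_among = 0,
                ss_within = 0, seed = as.integer(seed), exact = exact)
    class(res) <- "permanova_result"
    return(res)
  }

  f_perm_of <- function(g) {
    ssw <- .ss_within(d2, g)
    .pseudo_f(ss_total - ssw, ssw, a, n)
  }

  if (exact) {
    perms <- .multiset_permutations(groups)
    f_all <- vapply(perms, f_perm_of, numeric(1))
    ge <- sum(f_all >= f_obs | (is.nan(f_all) & is.nan(f_obs)))
    p <- ge / length(perms)
    m <- length(perms)
  } else {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    ge <- 0L
    for (i in seq_len(n_permutations)) {
      if (f_perm_of(sample(groups)) >= f_obs) ge <- ge + 1L
    }
    p <- (1 + ge) / (1 + n_permutations)
    m <- n_permutations
  }

  res <- list(f_stat = f_obs, p_value = p, n_permutations = as.integer(m),
              group_sizes = sizes, ss_total = ss_total, ss_among = ss_among,
              ss_within = ss_within, seed = as.integer(seed), exact = exact)
  class(res) <- "permanova_result"
  res
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("One-way PERMANOVA (",
      if (x$exact) "exact enumeration" else
        paste0(x$n_permutations, " permutations"),
      ")\n", sep = "")
  cat("  groups:", paste(x$group_sizes, collapse = " / "), "\n")
  cat(sprintf("  pseudo-F = %.4g, p = %.4g\n", x$f_stat, x$p_value))
  cat(sprintf("  SS among = %.4g, within = %.4g, total = %.4g\n",
              x$ss_among, x$ss_within, x$ss_total))
  invisible(x)
}

#' Compare a per-sample metric between supply groups
#'
#' Convenience wrapper: builds the Euclidean distance matrix on one summary
#' metric (optionally log10-transformed with a small offset, since cumulative
#' quotients are right-skewed over orders of magnitude) and runs
#' [permanova_oneway()] against the supply class labels.
#'
#' @param summaries per-sample summary data.frame carrying `supply_class`.
#' @param metric column name to compare (e.g. `"sum_tq"`).
#' @param n_permutations,seed passed to [permanova_oneway()].
#' @param transform `"identity"` (default) or `"log10"` (uses
#'   log10(x + offset)).
#' @param offset offset for the log transform (default 1e-8).
#' @return a `permanova_result`.
#' @export
compare_supply_groups <- function(summaries, metric, n_permutations = 9999,
                                  seed = 1,
                                  transform = c("identity", "log10"),
                                  offset = 1e-8) {
  transform <- match.arg(transform)
  x <- summaries[[metric]]
  if (is.null(x)) stop("metric column not found: ", metric)
  if (transform == "log10") x <- log10(x + offset)
  permanova_oneway(euclidean_distances(x), summaries$supply_class,
                   n_permutations = n_permutations, seed = seed)
}
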