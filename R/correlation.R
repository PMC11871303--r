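#' Spearman rank correlation with a two-sided p-value
#'
#' Ranks both vectors with average ranks for ties and computes the Pearson
#' correlation of the ranks. The two-sided p-value is, by default,
#' computed exactly for small samples -- full enumeration of all `n!`
#' permutations, counting the fraction with `|s_perm| >= |s_obs|` -- and
#' by the t-approximation with `n - 2` degrees of freedom
#' (`t = s * sqrt((n - 2) / (1 - s^2))`) for larger samples, where
#' enumeration is infeasible and the approximation is accurate. Pairs with
#' a missing value in either vector are deleted first.
#'
#' @param x,y Equal-length numeric vectors; >= 3 complete pairs required.
#' @param method `"auto"` (exact if `n <= exact_max`, else t), `"exact"`,
#'   or `"t"`.
#' @param exact_max Largest n for automatic exact enumeration.
#' @return One-row data frame of class `correlation_result`: `s`,
#'   `p_two_sided`, `n_used`, `method`, `flag` (`"constant_input"` when a
#'   vector is constant after deletion, with `s` and `p` set `NA`).
#' @examples
#' spearman(1:5, c(1, 3, 2, 5, 4))  # s = 0.8
#' @export
spearman <- function(x, y, method = c("auto", "exact", "t"), exact_max = 9L) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_invalid("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- data.frame(s = NA_real_, p_two_sided = NA_real_, n_used = n,
                      method = "none", flag = "constant_input",
                      stringsAsFactors = FALSE)
    class(out) <- c("correlation_result", "data.frame")
    return(out)
  }
  rx <- rank(x); ry <- rank(y)
  s <- stats::cor(rx, ry)
  use_exact <- method == "exact" || (method == "auto" && n <= exact_max)
  if (use_exact) {
    # explicit "exact" above the enumeration ceiling falls back to a
    # seeded Monte-Carlo permutation draw
    p <- exact_permutation_p(x, y, max_n = exact_max, allow_mc = n > exact_max)
    meth <- if (n <= exact_max) "exact permutation" else "mc permutation"
  } else {
    p <- spearman_p_t(s, n)
    meth <- "t-approximation"
  }
  out <- data.frame(s = s, p_two_sided = p, n_used = n, method = meth,
                    flag = "", stringsAsFactors = FALSE)
  class(out) <- c("correlation_result", "data.frame")
  out
}

# two-sided p from the t-approximation with n-2 df; |s| = 1 maps to the
# smallest representable positive probability to keep p in (0, 1]
spearman_p_t <- function(s, n) {
  if (abs(s) >= 1) return(.Machine$double.xmin)
  tstat <- s * sqrt((n - 2) / (1 - s^2))
  max(2 * stats::pt(-abs(tstat), df = n - 2), .Machine$double.xmin)
}

# all permutations of 1..n as an n! x n matrix (recursive construction)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    block <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Exact permutation p-value for the Spearman coefficient
#'
#' Enumerates all `n!` permutations of `y` and reports the fraction whose
#' Spearman coefficient has absolute value at least `|s_obs|` (within a
#' small numeric tolerance). This is the reference convention for the
#' two-sided test: the probability that randomly paired values would show
#' at least as strong a monotone association.
#'
#' @param x,y Equal-length numeric vectors without missing values.
#' @param max_n Refuse enumeration above this n (default 9); larger
#'   samples should use the t-approximation or a seeded Monte-Carlo draw
#'   ([spearman()] handles this automatically).
#' @param n_mc,mc_seed Monte-Carlo fallback controls used only when
#'   explicitly requested via `allow_mc = TRUE`.
#' @param allow_mc If `TRUE` and `n > max_n`, estimate the p-value from
#'   `n_mc` seeded random permutations instead of erroring.
#' @return Two-sided permutation probability in (0, 1].
#' @export
exact_permutation_p <- function(x, y, max_n = 9L, allow_mc = FALSE,
                                n_mc = 1e5, mc_seed = 1L) {
  n <- length(x)
  if (length(y) != n) stop_invalid("`x` and `y` must have equal length")
  rx <- rank(x); ry <- rank(y)
  s_obs <- stats::cor(rx, ry)
  tol <- 1e-9
  if (n > max_n) {
    if (!allow_mc) {
      stop_invalid("n > max_n: enumeration infeasible; use allow_mc = TRUE for a seeded Monte-Carlo estimate")
    }
    s_perm <- with_seed(mc_seed, replicate(n_mc, stats::cor(rx, sample(ry))))
    return((1 + sum(abs(s_perm) >= abs(s_obs) - tol)) / (1 + n_mc))
  }
  perms <- permutations_of(n)
  rx_c <- rx - mean(rx)
  denom <- sqrt(sum(rx_c^2) * sum((ry - mean(ry))^2))
  s_perm <- (matrix(ry[perms], nrow(perms), n) %*% rx_c) / denom
  mean(abs(s_perm) >= abs(s_obs) - tol)
}

#' Assemble a conformation-activity (CAR) table
#'
#' Joins the per-ligand ensemble summary (population-weighted shift) with
#' the per-ligand functional profile into the table on which pairwise
#' conformation-activity correlations are computed. Rows are matched by
#' `ligand_id`; ligands absent from either side keep `NA`s and are removed
#' pairwise by [correlation_matrix()].
#'
#' @param ensemble Data frame from [ensemble_table()].
#' @param profiles Data frame with `ligand_id` and functional columns
#'   (efficacies, affinities, bias factors, reporter activity, expression).
#' @return Data frame of class `car_table`, one row per ligand.
#' @export
car_table <- function(ensemble, profiles) {
  out <- merge(ensemble[, c("ligand_id", "delta_bar_H", "p_rep")], profiles,
               by = "ligand_id", all = TRUE)
  class(out) <- c("car_table", "data.frame")
  out
}

#' Pairwise Spearman correlation matrix of a CAR table
#'
#' All pairwise Spearman correlations between the numeric columns of the
#' table, with pairwise-complete observations, per-cell sample sizes, and
#' two-sided p-values. No multiple-comparison adjustment is applied; raw
#' p-values are reported together with `n_used` so readers can apply their
#' own. Columns with fewer than 3 complete pairs against a partner are
#' flagged `NA` for that cell.
#'
#' @param table A [car_table()] or any data frame; non-numeric columns and
#'   `ligand_id` are ignored.
#' @param method Passed to [spearman()].
#' @return List of class `car_correlations` with matrices `s`, `p`, `n`
#'   and a long-format data frame `pairs` (`col_a`, `col_b`, `s`, `p`,
#'   `n`, `method`).
#' @export
correlation_matrix <- function(table, method = "auto") {
  num <- table[, setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                         "ligand_id"), drop = FALSE]
  cols <- names(num)
  k <- length(cols)
  if (k < 2L) stop_invalid("need >= 2 numeric columns")
  s <- matrix(NA_real_, k, k, dimnames = list(cols, cols))
  p <- s; nmat <- matrix(0L, k, k, dimnames = list(cols, cols))
  pairs <- list()
  for (i in seq_len(k)) {
    s[i, i] <- 1; nmat[i, i] <- sum(is.finite(num[[i]]))
    for (j in seq_len(k)) {
      if (j <= i) next
      ok <- is.finite(num[[i]]) & is.finite(num[[j]])
      if (sum(ok) < 3L) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          col_a = cols[i], col_b = cols[j], s = NA_real_, p = NA_real_,
          n = sum(ok), method = "insufficient_pairs", stringsAsFactors = FALSE)
        next
      }
      res <- spearman(num[[i]][ok], num[[j]][ok], method = method)
      s[i, j] <- s[j, i] <- res$s
      p[i, j] <- p[j, i] <- res$p_two_sided
      nmat[i, j] <- nmat[j, i] <- res$n_used
      pairs[[length(pairs) + 1L]] <- data.frame(
        col_a = cols[i], col_b = cols[j], s = res$s, p = res$p_two_sided,
        n = res$n_used, method = res$method, stringsAsFactors = FALSE)
    }
  }
  structure(list(s = s, p = p, n = nmat, pairs = do.call(rbind, pairs)),
            class = "car_correlations")
}

#' @export
print.car_correlations <- function(x, digits = 2, ...) {
  cat("Pairwise Spearman correlation matrix:\n")
  print(round(x$s, digits))
  invisible(x)
}

#' Rank ligands by a profile column
#'
#' Stable descending sort of the table by the given column (the convention
#' used to number a ligand series by corepressor-recruitment efficacy);
#' ties are broken by `ligand_id`.
#'
#' @param table Data frame with `ligand_id` and the ranking column.
#' @param by Column name to rank on.
#' @return Character vector of `ligand_id` in rank order, with the numeric
#'   rank as names.
#' @export
rank_ligands <- function(table, by) {
  if (!by %in% names(table)) stop_invalid("column `", by, "` not present")
  ord <- order(-table[[by]], table$ligand_id)
  stats::setNames(table$ligand_id[ord], seq_along(ord))
}
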