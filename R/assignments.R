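#' Chemical shift perturbation distance between two amide peaks
#'
#' The scaled Euclidean distance in the (1H, 15N) plane,
#' `sqrt(dH^2 + (alpha_N * dN)^2)`, with the 15N difference scaled by
#' `alpha_N` to account for the wider 15N shift range. The community
#' default is `alpha_N = 0.14` (0.2 for glycines).
#'
#' @param delta_ref,delta_obs Length-2 numeric vectors `(delta_H, delta_N)`
#'   in ppm.
#' @param alpha_N 15N scaling factor.
#' @return CSP distance in ppm (>= 0).
#' @examples
#' csp(c(8.0, 110), c(8.03, 110.2), alpha_N = 0.2)  # 0.05
#' @export
csp <- function(delta_ref, delta_obs, alpha_N = 0.14) {
  if (!all(is.finite(c(delta_ref, delta_obs, alpha_N)))) {
    stop_invalid("CSP inputs must be finite")
  }
  sqrt((delta_obs[1] - delta_ref[1])^2 + (alpha_N * (delta_obs[2] - delta_ref[2]))^2)
}

# Hungarian algorithm (O(n^3) Jonker-Volgenant style potentials) for a
# square cost matrix; returns for each row the assigned column. Written
# for the modest peak-list sizes of assignment transfer.
hungarian_assign <- function(cost) {
  n <- nrow(cost)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)  # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(INF, n + 1L)
    used <- logical(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0 + 0L] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 1L:(n + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assignment <- integer(n)
  for (j in 2L:(n + 1L)) if (p[j] > 0L) assignment[p[j]] <- j - 1L
  assignment
}

#' Transfer assignments by minimum chemical shift perturbation
#'
#' Matches an unassigned observed peak list to an assigned reference list
#' by globally minimising the total CSP distance over one-to-one matchings
#' (Hungarian algorithm), subject to every accepted link having CSP at
#' most `max_csp`. Links exceeding the threshold are reported as
#' unmatched, the standard behaviour when a residue's peak has moved too
#' far between ligand-bound states for a confident transfer.
#'
#' @param reference Data frame with `residue_id`, `center_H`, `center_N`.
#' @param observed Data frame with `center_H`, `center_N` (a `peak_id`
#'   column is added if absent).
#' @param alpha_N 15N scaling factor for [csp()].
#' @param max_csp Maximum CSP (ppm) for an accepted link.
#' @return List of class `assignment_transfer`: `mapping` (data frame
#'   `residue_id`, `peak_id`, `csp`; `peak_id` `NA` for unmatched
#'   residues), `total_csp`, `alpha_N`, `max_csp`.
#' @export
transfer_assignments <- function(reference, observed, alpha_N = 0.14,
                                 max_csp = 0.1) {
  if (nrow(reference) == 0L || nrow(observed) == 0L) {
    stop_invalid("reference and observed peak lists must be non-empty")
  }
  if (is.null(observed$peak_id)) observed$peak_id <- seq_len(nrow(observed))
  nr <- nrow(reference); no <- nrow(observed)
  BIG <- 1e6  # cost of leaving a residue unmatched; >> any admissible CSP
  d <- matrix(BIG, nr, no)
  for (i in seq_len(nr)) for (j in seq_len(no)) {
    dij <- csp(c(reference$center_H[i], reference$center_N[i]),
               c(observed$center_H[j], observed$center_N[j]), alpha_N)
    if (dij <= max_csp) d[i, j] <- dij
  }
  n <- max(nr, no)
  cost <- matrix(BIG, n, n)
  cost[seq_len(nr), seq_len(no)] <- d
  assigned <- hungarian_assign(cost)
  mapping <- data.frame(residue_id = reference$residue_id,
                        peak_id = rep(NA, nr), csp = NA_real_,
                        stringsAsFactors = FALSE)
  for (i in seq_len(nr)) {
    j <- assigned[i]
    if (j <= no && d[i, j] < BIG) {
      mapping$peak_id[i] <- observed$peak_id[j]
      mapping$csp[i] <- d[i, j]
    }
  }
  structure(list(mapping = mapping,
                 total_csp = sum(mapping$csp, na.rm = TRUE),
                 alpha_N = alpha_N, max_csp = max_csp),
            class = "assignment_transfer")
}

#' @export
print.assignment_transfer <- function(x, ...) {
  matched <- sum(!is.na(x$mapping$peak_id))
  cat(sprintf("Assignment transfer: %d/%d residues matched (total CSP %.4f ppm, max_csp %.3g)\n",
              matched, nrow(x$mapping), x$total_csp, x$max_csp))
  invisible(x)
}
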