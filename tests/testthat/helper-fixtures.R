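# Shared fixture builders. Everything is generated in code; no binary data.

# noiseless spectrum containing a single 2D Lorentzian
single_peak_spectrum <- function(A = 100, cH = 8.2, cN = 109.5,
                                 wH = 0.02, wN = 0.15,
                                 range_H = c(7.9, 8.5), range_N = c(108, 111),
                                 n_H = 181, n_N = 121) {
  axH <- seq(range_H[1], range_H[2], length.out = n_H)
  axN <- seq(range_N[1], range_N[2], length.out = n_N)
  lh <- 1 / (1 + (2 * (axH - cH) / wH)^2)
  ln <- 1 / (1 + (2 * (axN - cN) / wN)^2)
  spectrum2d(A * outer(lh, ln), axH, axN)
}

# minimal fixed-width PDB text for C-alpha traces; `models` is a list of
# n x 3 matrices, `alt` an optional character vector per atom
pdb_text <- function(resno, models, chain = "A", alt = NULL) {
  if (!is.list(models)) models <- list(models)
  lines <- character(0)
  serial <- 1L
  multi <- length(models) > 1L
  for (m in seq_along(models)) {
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", m))
    xyz <- models[[m]]
    for (i in seq_along(resno)) {
      a <- if (is.null(alt)) " " else alt[i]
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA %sALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, a, chain, resno[i], xyz[i, 1], xyz[i, 2], xyz[i, 3]))
      serial <- serial + 1L
    }
    if (multi) lines <- c(lines, "ENDMDL")
  }
  c(lines, "END")
}

write_pdb_fixture <- function(resno, models, chain = "A", alt = NULL) {
  path <- tempfile(fileext = ".pdb")
  writeLines(pdb_text(resno, models, chain, alt), path)
  path
}

# proper random rotation matrix (det +1)
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# default anchors matching residue_state_shifts()
default_anchors <- function() {
  r <- residue_state_shifts()
  list(rep = c(r$delta_H_rep, r$delta_N_rep),
       act = c(r$delta_H_act, r$delta_N_act))
}
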