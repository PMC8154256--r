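# shared helpers for the test-suite

R_GAS <- kdentropy::gas_constant()

riemann_mass <- function(pdf_obj) sum(pdf_obj$pdf) * pdf_obj$grid$spacing

# naive O(n^2) DCT-II, the transform-domain reference
dct2_naive <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k)
    2 * sum(x * cos(pi * k * (2 * (0:(n - 1)) + 1) / (2 * n))),
    numeric(1))
}

# mean absolute relative entropy error (%) over Gaussian fixtures
gaussian_error_pct <- function(n, seeds, ...) {
  errs <- vapply(seeds, function(s) {
    fx <- generate_fixture("gaussian", n, seed = s)
    est <- kde_entropy(fx$values, ...)
    100 * abs(est$value - fx$true_entropy) / abs(fx$true_entropy)
  }, numeric(1))
  mean(errs)
}

# write a small cpptraj-style dihedral table and return its path
write_cpptraj_fixture <- function(angles_by_series, path = tempfile(fileext = ".dat")) {
  nm <- names(angles_by_series)
  n <- length(angles_by_series[[1L]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#Frame", paste(nm, collapse = " ")), con)
  for (i in seq_len(n)) {
    writeLines(paste(i, paste(sprintf("%.6f",
      vapply(angles_by_series, `[`, numeric(1), i)), collapse = " ")), con)
  }
  path
}

# minimal synthetic PDB: one CA atom per residue
write_toy_pdb <- function(residues, path = tempfile(fileext = ".pdb")) {
  lines <- c("HEADER    SYNTHETIC TOY STRUCTURE")
  for (i in seq_along(residues)) {
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      i, residues[i], i * 1.0, 0, 0))
  }
  writeLines(c(lines, "END"), path)
  path
}
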