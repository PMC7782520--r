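# Shared fixtures and independent oracles.  Expensive scenario pipelines are
# memoised so several test files can share one run.

.fx_cache <- new.env(parent = emptyenv())

cached_scenario_result <- function(name, seed = 7) {
  key <- paste(name, seed, sep = "#")
  if (is.null(.fx_cache[[key]])) {
    .fx_cache[[key]] <- run_scenario(name, seed = seed)
  }
  .fx_cache[[key]]
}

random_map <- function(n, seed, voxel = 1, origin = c(0, 0, 0)) {
  set.seed(seed)
  density_map(array(rnorm(n^3), c(n, n, n)), voxel, origin)
}

# Brute-force FSC oracle: 3D DFT by explicit DFT-matrix products, then an
# element-by-element loop binning coefficients at integer shell radii.
# Independent of the package's fft + rowsum path.
brute_fsc <- function(a, b) {
  n <- dim(a)[1]
  W <- exp(-2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
  dft3 <- function(x) {
    y <- apply(x, c(2, 3), function(v) W %*% v)
    dim(y) <- c(n, n, n)
    y <- aperm(apply(y, c(1, 3), function(v) W %*% v), c(2, 1, 3))
    aperm(apply(y, c(1, 2), function(v) W %*% v), c(2, 3, 1))
  }
  fa <- dft3(a)
  fb <- dft3(b)
  kidx <- function(f) ifelse(f - 1 <= n / 2, f - 1, f - 1 - n)
  ns <- n %/% 2 + 1
  num <- den1 <- den2 <- numeric(ns)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    r <- round(sqrt(kidx(i)^2 + kidx(j)^2 + kidx(k)^2))
    if (r <= n %/% 2) {
      s <- r + 1
      num[s] <- num[s] + Re(fa[i, j, k] * Conj(fb[i, j, k]))
      den1[s] <- den1[s] + abs(fa[i, j, k])^2
      den2[s] <- den2[s] + abs(fb[i, j, k])^2
    }
  }
  num / sqrt(den1 * den2)
}

# Tiny hand-written structure fixtures.
fixture_pdb_lines <- function() {
  c("REMARK synthetic three-atom fixture",
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 20.00           N",
    "ATOM      2  CA  ALA A   1       2.000   2.500   3.500  1.00 21.00           C",
    "ATOM      3  C   ALA A   1       3.200   1.900   4.100  1.00 22.00           C",
    "END")
}

fixture_cif_lines <- function() {
  c("data_synthetic_fixture",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 1.000 2.000 3.000 1.00 20.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 2.000 2.500 3.500 1.00 21.00 ? 1 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 3.200 1.900 4.100 1.00 22.00 ? 1 ALA A C 1")
}

single_atom_model <- function(x = 15, y = 15, z = 15, element = "C") {
  atomic_model(tibble::tibble(
    name = "CA", res_name = "ALA", chain = "A", res_seq = 1,
    x = x, y = y, z = z, element = element
  ))
}

# A synthetic fsc_curve for crossing tests.
manual_curve <- function(freq, fsc, voxel = 1) {
  cv <- tibble::tibble(shell = seq_along(freq) - 1L, shell_freq = freq,
                       fsc = fsc, n_terms = 1L)
  attr(cv, "voxel_size") <- voxel
  attr(cv, "nyquist_res") <- 2 * voxel
  class(cv) <- c("fsc_curve", class(cv))
  cv
}
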