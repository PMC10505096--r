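# Independent oracles used to cross-check the implementation. These are
# deliberately naive re-implementations that share no code with the package.

# Brute-force translocation counter: a literal per-frame walk of the
# three-region rule, one frame at a time, no run-length compression.
brute_force_crossings <- function(series, geom) {
  z <- series$z
  n <- nrow(z); k <- ncol(z)
  count <- 0L
  for (j in seq_len(k)) {
    state <- NA_integer_
    jumped <- FALSE
    for (i in seq_len(n)) {
      if (i > 1L && abs(z[i, j] - z[i - 1L, j]) > series$box_z[i] / 2)
        jumped <- TRUE
      r <- if (z[i, j] <= geom$lower_plane) 0L else
        if (z[i, j] >= geom$upper_plane) 2L else 1L
      if (r == 1L) next
      if (is.na(state)) {
        state <- r; jumped <- FALSE
      } else if (r == state) {
        jumped <- FALSE
      } else {
        if (!jumped) count <- count + 1L
        state <- r; jumped <- FALSE
      }
    }
  }
  count
}

# OLS through the normal equations, no lm().
ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(c = beta[1L], m = beta[2L])
}

# Random wrapped walk fixture: k solutes random-walking in a periodic box,
# occasionally teleported across the periodic boundary to exercise the
# jump-transfer rule.
random_walk_series <- function(n = 60, k = 2, box_z = 12, step = 1.2,
                               jump_prob = 0.05) {
  z <- matrix(0, n, k)
  for (j in seq_len(k)) {
    zj <- runif(1, -box_z / 2, box_z / 2)
    for (i in seq_len(n)) {
      zj <- zj + rnorm(1, 0, step)
      if (runif(1) < jump_prob) zj <- zj + box_z / 2 + runif(1, 0, 2)
      zj <- ((zj + box_z / 2) %% box_z) - box_z / 2
      z[i, j] <- zj
    }
  }
  zseries(seq_len(n), z, box_z, temperature = 440)
}

# Minimal multi-model PDB writer for adapter tests: one atom per solute
# copy (resid SOL) plus phosphate marker atoms for the two leaflets.
# z coordinates given in nm, written in Angstrom.
write_pdb_fixture <- function(path, z_sol_nm, lipid_z_nm = c(-2, 2),
                              box_z_nm = 12, n_lipid_per_leaflet = 4) {
  z_sol_nm <- as.matrix(z_sol_nm)
  nfr <- nrow(z_sol_nm); nsol <- ncol(z_sol_nm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    50, 50, box_z_nm * 10, 90, 90, 90), con)
  atom_line <- function(serial, name, resid, resno, xyz, elem) {
    sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, resid, resno, xyz[1], xyz[2], xyz[3], 1, 0, elem)
  }
  for (m in seq_len(nfr)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    for (s in seq_len(nsol)) {
      serial <- serial + 1L
      writeLines(atom_line(serial, "C1", "SOL", s,
                           c(1, 1, z_sol_nm[m, s] * 10), "C"), con)
    }
    for (leaf in c(1, 2)) {
      for (l in seq_len(n_lipid_per_leaflet)) {
        serial <- serial + 1L
        writeLines(atom_line(serial, "P", "LIP", 100 + leaf * 10 + l,
                             c(l, l, lipid_z_nm[leaf] * 10), "P"), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Random valid zseries for round-trip property tests.
random_zseries <- function(n = 20, k = 2, with_lipid = TRUE) {
  box <- runif(1, 8, 15)
  zseries(
    times = cumsum(runif(n, 0.01, 1)),
    z = matrix(runif(n * k, -box / 2, box / 2), n, k),
    box_z = box,
    temperature = runif(1, 300, 500),
    lipid_ref_z = if (with_lipid)
      cbind(runif(n, -3, -1), runif(n, 1, 3)),
    label = paste0("cmp", sample(1000, 1))
  )
}
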