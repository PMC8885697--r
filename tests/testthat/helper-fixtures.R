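# shared fixture builders for the test suite

prop_cols <- c("glu_potency", "gly_potency", "deact_tau", "current_density",
               "open_prob", "surface_level")

# minimal complete property table: WT plus mutants at given fold changes
make_property_table <- function(fold = list()) {
  wt <- c(glu_potency = 0.5, gly_potency = 1, deact_tau = 50,
          current_density = 150, open_prob = 0.5, surface_level = 1)
  rows <- list(tibble::tibble(mutation = "WT", !!!as.list(wt)))
  for (nm in names(fold)) {
    v <- wt * fold[[nm]]
    rows[[length(rows) + 1]] <- tibble::tibble(mutation = nm, !!!as.list(v))
  }
  as_property_table(dplyr::bind_rows(rows))
}

# property CSV on disk (EC50 dialect) for reader tests
write_property_csv <- function(path, tbl_df) {
  write.csv(tbl_df, path, row.names = FALSE, na = "")
  path
}

# flat sweep with an optional injected waveform
make_sweep <- function(y, v_hold = -100, rs = 10, cm = 100, fs = 25000,
                       t0 = 0.05) {
  new_sweep(y, fs_hz = fs, v_hold_mV = v_hold, rs_MOhm = rs, cm_pF = cm,
            t0_stim_s = t0)
}

# O(n^2) pair-counting oracle for Kendall tau-b, independent of the package
tau_b_oracle <- function(x, y) {
  n <- length(x)
  C <- D <- Tx <- Ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (dx == 0 && dy == 0) { Tx <- Tx + 1; Ty <- Ty + 1 }
    else if (dx == 0) Tx <- Tx + 1
    else if (dy == 0) Ty <- Ty + 1
    else if (dx * dy > 0) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - Tx) * (n0 - Ty))
}

# passive-only density set
passive_densities <- function(leak = 1e-4) {
  d <- default_densities()
  for (r in names(d)) {
    d[[r]][c("na", "kdr", "ka", "ih", "car", "kca")] <- 0
    d[[r]]["leak"] <- leak
  }
  d
}
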