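# Shared fixtures: built in code at test time.

std_default <- default_standards()

# Random valid measurement vectors over the full registry, spanning a few
# orders of magnitude around the permissible limits.
random_values <- function(standards = std_default) {
  p <- standards$parameters
  v <- stats::setNames(numeric(nrow(p)), p$code)
  for (i in seq_len(nrow(p))) {
    base <- if (!is.na(p$permissible_limit[i])) p$permissible_limit[i] else 10
    v[i] <- stats::runif(1, 0, 4) * base
  }
  v["ph"] <- stats::runif(1, 1, 13)
  v["sd"] <- stats::runif(1, 0.1, 6)
  v["tp"] <- stats::runif(1, 0.5, 120)
  v["chla"] <- stats::runif(1, 0.5, 150)
  v
}

# Tiny deterministic wide sample table (2 sites x 2 phases).
tiny_samples <- function() {
  m <- damodar_phase_stats()
  pre <- phase_means("pre_lockdown", m)
  lock <- phase_means("lockdown", m)
  rows <- rbind(pre, pre * 1.1, lock, lock * 0.9)
  df <- tibble::tibble(site_id = c("S1", "S2", "S1", "S2"),
                       phase = rep(c("pre_lockdown", "lockdown"), each = 2))
  cbind(df, tibble::as_tibble(rows))
}
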