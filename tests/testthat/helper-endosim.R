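# Shared fixtures: small-scale settings and canonical mechanisms.

mech_b <- function() mechanism(id = "ME+/CX-/EU")
mech_c <- function() mechanism(id = "ME+/CX+/A")

tiny_settings <- function(n_initial = 100, n_runs = 2, seed = 1, ...) {
  sim_settings(n_initial = n_initial, n_runs = n_runs, seed = seed, ...)
}

# A one-row population data.frame with explicit fields, for operation tests.
one_cell <- function(regime = "OMEGA", a_value = 0.5, age = 0,
                     life_span = 1000, cycle_position = 0,
                     proliferation_competent = FALSE,
                     proliferation_clock = 0, proliferation_window = 1000,
                     phenotype = "HESC", stage = 1L,
                     prop_1 = 0, prop_2 = 0, prop_3 = 0) {
  data.frame(regime = regime, a_value = a_value, age = age,
             life_span = life_span, cycle_position = cycle_position,
             proliferation_competent = proliferation_competent,
             proliferation_clock = proliferation_clock,
             proliferation_window = proliferation_window,
             phenotype = phenotype, stage = stage,
             prop_1 = prop_1, prop_2 = prop_2, prop_3 = prop_3,
             stringsAsFactors = FALSE)
}

# Brute-force histogram distance: tabulates bin membership element by element
# with explicit comparisons (independent of findInterval/tabulate).
brute_histogram_distance <- function(nominal, perturbed, edges) {
  k <- length(edges) - 1L
  share <- function(x) {
    counts <- numeric(k + 2)
    for (v in x) {
      if (v < edges[1]) {
        counts[1] <- counts[1] + 1
      } else if (v > edges[k + 1]) {
        counts[k + 2] <- counts[k + 2] + 1
      } else {
        for (b in seq_len(k)) {
          hi <- edges[b + 1]
          in_bin <- if (b < k) (v >= edges[b] && v < hi)
                    else (v >= edges[b] && v <= hi)
          if (in_bin) {
            counts[b + 1] <- counts[b + 1] + 1
            break
          }
        }
      }
    }
    counts / length(x)
  }
  sum(abs(share(nominal) - share(perturbed)))
}
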