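# Shared fixtures: small registries with explicitly configured backbone
# masses (correctness never depends on the shipped default masses), and an
# independent brute-force enumeration oracle.

# single 20 kDa backbone with mandatory pyroglutamate
fixture_registry <- function() {
  variant_registry(list(
    backbone_variant("V1", 20000.00, modifications = "pyroglutamate")
  ))
}

# two bare backbones (no modifications), 150 Da apart
bare_registry <- function(masses = c(V1 = 20000.00, V2 = 20150.00)) {
  variant_registry(lapply(names(masses), function(nm) {
    backbone_variant(nm, masses[[nm]], modifications = character(0))
  }))
}

# brute-force triple-loop enumeration over (variant, N, F, S), filtered by
# the scalar validate_composition() and the mass window; deliberately
# independent of enumerate_candidates() internals
oracle_enumerate <- function(registry, k, window, sa_count = NULL,
                             table = residue_mass_table()) {
  rows <- list()
  for (vn in names(registry$variants)) {
    v <- registry$variants[[vn]]
    mand <- Filter(function(m) registry$modifications[[m]]$mandatory,
                   v$modifications)
    delta <- if (length(mand)) {
      sum(vapply(mand, function(m) registry$modifications[[m]]$delta_Da,
                 numeric(1)))
    } else 0
    s_vals <- if (is.null(sa_count)) k$sa_min:k$sa_max else sa_count
    for (N in k$n_min:k$n_max) {
      for (F in 0:k$max_fucose) {
        for (S in s_vals) {
          cc <- glycan_composition(N + hex_offset(k), N, F, S)
          if (!validate_composition(cc, k)$pass) next
          mass <- v$backbone_mass_Da + composition_mass(cc, table) + delta
          if (mass >= window[1] && mass <= window[2]) {
            rows[[length(rows) + 1L]] <- data.frame(
              variant = vn, composition = format(cc),
              theoretical_mass_Da = mass, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(variant = character(0), composition = character(0),
                      theoretical_mass_Da = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$variant, out$composition), , drop = FALSE]
}

# a random small registry + constraint set + window for oracle testing
random_enumeration_case <- function() {
  n_var <- sample(1:3, 1)
  reg <- variant_registry(lapply(seq_len(n_var), function(i) {
    backbone_variant(sprintf("V%d", i),
                     round(stats::runif(1, 15000, 25000), 2),
                     modifications = sample(c("pyroglutamate", "none"), 1))
  }))
  k <- composition_constraints(
    max_fucose = sample(0:4, 1),
    sa_min = sample(0:5, 1), sa_max = sample(8:20, 1),
    n_min = sample(10:14, 1), n_max = sample(18:26, 1),
    enforce_sa_le_antennae = sample(c(TRUE, FALSE), 1))
  center <- stats::runif(1, 24000, 40000)
  width <- stats::runif(1, 0.5, 400)
  sa <- if (stats::runif(1) < 0.5) sample(k$sa_min:k$sa_max, 1) else NULL
  list(registry = reg, constraints = k,
       window = c(center - width, center + width), sa_count = sa)
}

expect_same_candidates <- function(got, want) {
  key <- function(df) {
    paste(df$variant, df$composition, round(df$theoretical_mass_Da, 6))
  }
  expect_setequal(key(got), key(want))
}

# symmetric sialylation profile: configured mean SA exactly 16, branching
# support high enough that the antenna-capacity rule never truncates it
symmetric_sa_spec <- function(n = 400L, seed = 42L) {
  profile_spec(sa_distribution = triangular_weights(13, 19, 16),
               antenna_distribution = triangular_weights(29, 33, 31),
               n_proteoforms = n, seed = seed)
}
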