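# Shared fixtures: scaled-down simulated worlds and toy signatures.

small_config <- function(seed = 1L, n_genes = 400L, timepoints = "P5") {
  sim_config(n_genes = n_genes, timepoints = timepoints, seed = seed)
}

small_effects <- function(config, ...) {
  planted_effects(config, n_core = 40L, n_interaction = 30L, n_gonadal = 20L,
                  n_escapee = 8L, n_y_only = 6L, ...)
}

small_study <- function(seed = 1L, ...) {
  sc <- small_config(seed)
  eff <- small_effects(sc, ...)
  list(config = sc, effects = eff, study = simulate_murine_counts(sc, eff))
}

sig <- function(name, up = character(0), down = character(0)) {
  fcg_signature(name, up, down)
}

# random directional signature over a universe
random_signature <- function(name, universe, n_max = 8L) {
  n <- sample.int(n_max + 1L, 1L) - 1L
  genes <- sample(universe, n)
  n_up <- if (n > 0) sample.int(n + 1L, 1L) - 1L else 0L
  fcg_signature(name, up = genes[seq_len(n_up)],
                down = genes[setdiff(seq_len(n), seq_len(n_up))])
}

signature_genes <- function(s) c(s$up, s$down)

# Brute-force O(N) running-sum oracle for the weighted KS enrichment score.
oracle_es <- function(genes, metric, gene_set, p = 1) {
  hit <- genes %in% gene_set
  w <- abs(metric)^p
  nr <- sum(w[hit])
  run <- 0; best <- 0
  for (i in seq_along(genes)) {
    if (hit[i]) {
      run <- run + (if (nr > 0) w[i] / nr else 1 / sum(hit))
    } else {
      run <- run - 1 / (length(genes) - sum(hit))
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# brute-force per-gene membership oracle for the 4-way decomposition
oracle_decompose <- function(s_xxf, s_xxm, s_xyf, s_xym) {
  sigs <- list(XXF = s_xxf, XXM = s_xxm, XYF = s_xyf, XYM = s_xym)
  dir_of <- function(s, g) {
    if (g %in% s$up) 1L else if (g %in% s$down) -1L else 0L
  }
  universe <- unique(unlist(lapply(sigs, signature_genes)))
  regions <- list(A = character(0), B = character(0), C = character(0),
                  D = character(0), E = character(0))
  dirs <- list(A = integer(0), B = integer(0), C = integer(0),
               D = integer(0), E = integer(0))
  pair <- list(A = c("XXF", "XYF"), B = c("XXM", "XYM"),
               C = c("XXF", "XXM"), D = c("XYF", "XYM"))
  for (g in universe) {
    d <- vapply(sigs, dir_of, integer(1), g = g)
    in_e <- all(d != 0L) && length(unique(d)) == 1L
    if (in_e) {
      regions$E <- c(regions$E, g); dirs$E <- c(dirs$E, d[1])
      next
    }
    for (r in names(pair)) {
      d2 <- d[pair[[r]]]
      if (all(d2 != 0L) && d2[1] == d2[2]) {
        regions[[r]] <- c(regions[[r]], g)
        dirs[[r]] <- c(dirs[[r]], d2[1])
      }
    }
  }
  lapply(stats::setNames(names(regions), names(regions)), function(r) {
    o <- order(regions[[r]])
    data.frame(gene = as.character(regions[[r]][o]),
               direction = as.character(ifelse(dirs[[r]][o] > 0, "up",
                                               "down")),
               stringsAsFactors = FALSE)
  })
}
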