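#' Configuration of an induction (SCRaMbLE) pool
#'
#' Parameters of the stochastic per-cell model of one induction: a cell
#' carries nuclear Cre activity with probability `p_cre_active`; an active
#' cell accumulates a Poisson(`lambda_events`) number of recombination
#' events, each drawn by type from `type_weights` and uniformly over the
#' lox-site pairs applicable to the cell's current genotype, applied
#' sequentially; the reporter (GFP) flips irreversibly with probability
#' `p_reporter_flip` in active cells and leaks on with probability
#' `p_leak` in inactive ones. Reporter state and module events are
#' conditionally independent given Cre activity, so GFP+ cells with an
#' unrearranged module are allowed.
#'
#' @param n_cells Number of cells simulated.
#' @param lambda_events Mean per-cell event count (Poisson rate).
#' @param p_cre_active,p_reporter_flip,p_leak Probabilities in `[0, 1]`.
#' @param type_weights Named probabilities over
#'   `c(deletion, inversion, duplication)`; must sum to 1.
#' @param seed Optional integer seed (can also be given at call sites).
#' @return A list of class `pool_config`.
#' @export
pool_config <- function(n_cells = 10000L, lambda_events = 1.5,
                        p_cre_active = 0.6, p_reporter_flip = 0.9,
                        p_leak = 0.01,
                        type_weights = c(deletion = 0.35, inversion = 0.45,
                                         duplication = 0.20),
                        seed = NULL) {
  probs <- c(p_cre_active, p_reporter_flip, p_leak)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (!is.finite(lambda_events) || lambda_events < 0)
    stop("lambda_events must be >= 0")
  if (!setequal(names(type_weights), EVENT_TYPES))
    stop("type_weights must be named over deletion/inversion/duplication")
  type_weights <- type_weights[EVENT_TYPES]
  if (any(type_weights < 0) || abs(sum(type_weights) - 1) > 1e-8)
    stop("type_weights must be non-negative and sum to 1")
  structure(list(n_cells = as.integer(n_cells),
                 lambda_events = lambda_events,
                 p_cre_active = p_cre_active,
                 p_reporter_flip = p_reporter_flip,
                 p_leak = p_leak,
                 type_weights = type_weights,
                 seed = seed),
            class = "pool_config")
}

#' Growth/selection model for rearranged genotypes
#'
#' Maps a genotype to a relative growth rate. In `minus_his` medium every
#' `essential_segments` member must be present (copy number >= 1) for any
#' growth; the dosage response of `dosage_gene` is given by `mu_of_copy`,
#' a non-decreasing, saturating map from copy number to relative rate in
#' `[0, 1]` (copies beyond the largest key take the last value). The
#' default encodes a weakly expressed `HIS5`: one copy grows at 0.4 of
#' `mu_max`, two or more restore full growth. In `plus_his` medium there
#' is no selection (all viable genotypes grow at `mu_max`).
#'
#' @param medium `"minus_his"` or `"plus_his"`.
#' @param essential_segments Character vector of segment names that are
#'   essential in `minus_his`; `NULL` means all `gene_cassette` segments
#'   of the design in use.
#' @param mu_max Maximal growth rate (per generation, relative units).
#' @param dosage_gene Segment whose copy number modulates growth.
#' @param mu_of_copy Named numeric vector, names = copy numbers.
#' @return A list of class `fitness_model`.
#' @export
fitness_model <- function(medium = c("minus_his", "plus_his"),
                          essential_segments = NULL, mu_max = 1,
                          dosage_gene = "HIS5",
                          mu_of_copy = c("1" = 0.4, "2" = 1.0)) {
  medium <- match.arg(medium)
  if (!is.numeric(mu_of_copy) || is.null(names(mu_of_copy)))
    stop("mu_of_copy must be a named numeric vector (names = copy numbers)")
  cps <- as.integer(names(mu_of_copy))
  if (any(is.na(cps)) || is.unsorted(cps))
    stop("mu_of_copy names must be increasing copy numbers")
  if (is.unsorted(mu_of_copy))
    stop("mu_of_copy must be non-decreasing in copy number")
  if (any(mu_of_copy < 0) || any(mu_of_copy > 1))
    stop("mu_of_copy values must lie in [0, 1] (relative to mu_max)")
  if (!is.finite(mu_max) || mu_max <= 0) stop("mu_max must be positive")
  structure(list(medium = medium,
                 essential_segments = essential_segments,
                 mu_max = mu_max,
                 dosage_gene = dosage_gene,
                 mu_of_copy = mu_of_copy),
            class = "fitness_model")
}

#' Growth rate of a genotype under a fitness model
#'
#' @param genotype Signed integer vector or canonical key.
#' @param design A `module_design`.
#' @param model A [fitness_model()].
#' @return Numeric growth rate in `[0, mu_max]`.
#' @export
genotype_fitness <- function(genotype, design, model) {
  if (is.character(genotype)) genotype <- parse_key(genotype)
  if (model$medium == "plus_his") return(model$mu_max)
  counts <- copy_numbers(genotype, design)
  essentials <- model$essential_segments %||%
    design$segments$name[design$segments$role == "gene_cassette"]
  if (any(counts[essentials] == 0L)) return(0)
  dos <- counts[[model$dosage_gene]]
  cps <- as.integer(names(model$mu_of_copy))
  if (dos < min(cps)) return(0)
  # saturating lookup: copies beyond the largest listed key take its value,
  # unlisted intermediate copies take the largest listed key below them
  rel <- model$mu_of_copy[[max(which(cps <= dos))]]
  rel * model$mu_max
}

new_pool <- function(key, abundance, gfp_fraction) {
  df <- data.frame(key = as.character(key), abundance = as.numeric(abundance),
                   gfp_fraction = as.numeric(gfp_fraction),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$abundance, df$key), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("scramble_pool", "data.frame")
  df
}

#' Pool genotype frequencies
#'
#' @param pool A `scramble_pool` (data frame with columns `key`,
#'   `abundance`, `gfp_fraction`).
#' @return Named numeric vector of abundance shares summing to 1.
#' @export
pool_frequencies <- function(pool) {
  stopifnot(is.data.frame(pool), all(c("key", "abundance") %in% names(pool)))
  setNames(pool$abundance / sum(pool$abundance), pool$key)
}

#' Simulate one Cre induction of a cell pool
#'
#' Runs the per-cell model of [pool_config()] for `config$n_cells` cells
#' starting from `parental`, then aggregates cells by genotype key. The
#' result records, per genotype, the number of cells (abundance) and the
#' fraction of those cells that are GFP positive. Bit-reproducible given
#' `seed`.
#'
#' @param parental Signed integer vector; the starting genotype of every
#'   cell.
#' @param design A `module_design`.
#' @param config A [pool_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A `scramble_pool` data frame (`key`, `abundance`,
#'   `gfp_fraction`), sorted by decreasing abundance.
#' @export
#' @examples
#' d <- default_his_design(segment_length = 200, flank_length = 60)
#' p <- simulate_induction(parental_genotype(d), d,
#'                         pool_config(n_cells = 200), seed = 1)
#' head(p)
simulate_induction <- function(parental, design, config = pool_config(),
                               seed = NULL) {
  stopifnot(inherits(config, "pool_config"))
  parental <- check_genotype(parental, design)
  seed <- seed %||% config$seed
  if (is.null(seed)) stop("a seed is required (in config or as argument)")
  with_seed(stage_seed(seed, "induction"), {
    n <- config$n_cells
    active <- runif(n) < config$p_cre_active
    gfp <- ifelse(active,
                  runif(n) < config$p_reporter_flip,
                  runif(n) < config$p_leak)
    n_events <- ifelse(active, rpois(n, config$lambda_events), 0L)
    keys <- character(n)
    parental_key <- canonical_key(parental)
    w <- config$type_weights
    for (c_i in seq_len(n)) {
      if (n_events[c_i] == 0L) { keys[c_i] <- parental_key; next }
      g <- parental
      for (e_i in seq_len(n_events[c_i])) {
        m <- length(g)
        if (m == 0L) break  # nothing left to recombine
        type <- sample(EVENT_TYPES, 1L, prob = w)
        sites <- sort(sample.int(m + 1L, 2L) - 1L)
        g <- apply_event(g, recombination_event(type, sites[1], sites[2]))
      }
      keys[c_i] <- canonical_key(g)
    }
    ab <- tapply(rep(1, n), keys, sum)
    gf <- tapply(gfp, keys, mean)
    # positional alignment: tapply orders both by the same key levels
    # (name-based indexing would break on the empty genotype key "")
    stopifnot(identical(names(ab), names(gf)))
    new_pool(names(ab), as.numeric(ab), as.numeric(gf))
  })
}

#' FACS gate on the reporter
#'
#' Keeps the GFP-positive mass of each genotype: abundances are reweighted
#' by `gfp_fraction` and genotypes with no GFP+ mass are removed (their
#' cells were not sorted). After gating, `gfp_fraction` is 1 by
#' construction.
#'
#' @param pool A `scramble_pool`.
#' @return A gated `scramble_pool`.
#' @export
facs_gate <- function(pool) {
  stopifnot(is.data.frame(pool),
            all(c("key", "abundance", "gfp_fraction") %in% names(pool)))
  if (nrow(pool) == 0L) stop("empty pool")
  ab <- pool$abundance * pool$gfp_fraction
  keep <- ab > 0
  if (!any(keep)) stop("FACS gate is empty: no GFP-positive mass in the pool")
  new_pool(pool$key[keep], ab[keep], rep(1, sum(keep)))
}

#' Grow a pool under selection
#'
#' Deterministic exponential growth: each genotype's abundance is
#' multiplied by `2^(generations * mu / mu_max)` where `mu` is its
#' [genotype_fitness()]. Zero-fitness genotypes retain
#' `dead_carryover` of their abundance (default 0, i.e. they drop out;
#' a positive value models template amplified from dead or non-growing
#' cells). No new genotype keys can appear.
#'
#' @param pool A `scramble_pool`.
#' @param design A `module_design`.
#' @param model A [fitness_model()].
#' @param generations Non-negative number of generations.
#' @param dead_carryover Fraction of abundance retained by zero-fitness
#'   genotypes.
#' @return A `scramble_pool`.
#' @export
grow_select <- function(pool, design, model, generations = 20,
                        dead_carryover = 0) {
  stopifnot(is.data.frame(pool), inherits(model, "fitness_model"),
            generations >= 0, dead_carryover >= 0, dead_carryover <= 1)
  if (nrow(pool) == 0L) stop("empty pool")
  mu <- vapply(pool$key, genotype_fitness, numeric(1),
               design = design, model = model)
  factor <- ifelse(mu > 0, 2^(generations * mu / model$mu_max), dead_carryover)
  ab <- pool$abundance * factor
  keep <- ab > 0
  if (!any(keep))
    stop("all genotypes have zero fitness and dead_carryover is 0")
  new_pool(pool$key[keep], ab[keep], pool$gfp_fraction[keep])
}

#' Iterative induce / gate / select rounds
#'
#' Emulates iterative rearrangement cycles: each round takes the `top_k`
#' most abundant genotypes of the previous round's output (round 1 starts
#' from `parental`), re-induces each founder clone with cells allocated in
#' proportion to founder abundance, pools the results, gates on the
#' reporter and grows under selection.
#'
#' @param parental Starting genotype for round 1.
#' @param design A `module_design`.
#' @param config A [pool_config()].
#' @param model A [fitness_model()].
#' @param n_rounds Number of rounds (>= 1).
#' @param generations Selection generations per round.
#' @param top_k Number of founder genotypes carried into each round.
#' @param dead_carryover Passed to [grow_select()].
#' @param seed Integer seed; each round uses an independent substream.
#' @return A list with `pools` (list of per-round `scramble_pool`s) and
#'   `summary`, a data frame with one row per round: `round`,
#'   `dominant_key`, `dominant_freq`, `mean_dosage_copy`,
#'   `n_distinct_genotypes`.
#' @export
run_iterative_rounds <- function(parental, design, config = pool_config(),
                                 model = fitness_model(), n_rounds = 2L,
                                 generations = 20, top_k = 1L,
                                 dead_carryover = 0, seed = NULL) {
  stopifnot(n_rounds >= 1L, top_k >= 1L)
  seed <- seed %||% config$seed
  if (is.null(seed)) stop("a seed is required (in config or as argument)")
  founders <- data.frame(key = canonical_key(parental), weight = 1,
                         stringsAsFactors = FALSE)
  pools <- vector("list", n_rounds)
  summary_rows <- vector("list", n_rounds)
  dosage_id <- match(model$dosage_gene, design$segments$name)
  for (r in seq_len(n_rounds)) {
    round_seed <- stage_seed(seed, paste0("round", r))
    sub_pools <- lapply(seq_len(nrow(founders)), function(f) {
      n_f <- max(1L, round(config$n_cells * founders$weight[f]))
      cfg_f <- config
      cfg_f$n_cells <- as.integer(n_f)
      simulate_induction(parse_key(founders$key[f]), design, cfg_f,
                         seed = stage_seed(round_seed, founders$key[f]))
    })
    combined <- do.call(rbind, sub_pools)
    agg_ab <- tapply(combined$abundance, combined$key, sum)
    agg_gfpm <- tapply(combined$abundance * combined$gfp_fraction,
                       combined$key, sum)
    stopifnot(identical(names(agg_ab), names(agg_gfpm)))
    pool <- new_pool(names(agg_ab), as.numeric(agg_ab),
                     as.numeric(agg_gfpm) / as.numeric(agg_ab))
    pool <- facs_gate(pool)
    pool <- grow_select(pool, design, model, generations = generations,
                        dead_carryover = dead_carryover)
    pools[[r]] <- pool
    freqs <- pool_frequencies(pool)
    copies <- vapply(pool$key, function(k) {
      g <- parse_key(k)
      sum(abs(g) == dosage_id)
    }, numeric(1))
    summary_rows[[r]] <- data.frame(
      round = r,
      dominant_key = pool$key[1],
      dominant_freq = unname(freqs[1]),
      mean_dosage_copy = sum(freqs * copies),
      n_distinct_genotypes = nrow(pool),
      stringsAsFactors = FALSE
    )
    kk <- min(top_k, nrow(pool))
    founders <- data.frame(key = pool$key[seq_len(kk)],
                           weight = pool$abundance[seq_len(kk)] /
                             sum(pool$abundance[seq_len(kk)]),
                           stringsAsFactors = FALSE)
  }
  list(pools = pools, summary = do.call(rbind, summary_rows))
}

#' Write / read a pool as TSV
#'
#' Stable three-column schema `key`, `abundance`, `gfp_fraction` with a
#' header row.
#'
#' @param pool A `scramble_pool`.
#' @param path Output TSV path.
#' @export
write_pool <- function(pool, path) {
  write.table(as.data.frame(pool), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool
#' @export
read_pool <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(key = "character"))
  df$key[is.na(df$key)] <- ""  # empty genotype key round-trips as ""
  new_pool(df$key, df$abundance, df$gfp_fraction)
}
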