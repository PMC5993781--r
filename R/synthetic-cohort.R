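# Synthetic infant-cohort generator.
#
# Emulates the statistical structure the downstream analyses assume: ~12
# infants sampled near-daily over the first year, libraries with large spread,
# four dominant phyla with individual-specific trajectories, a planted
# Bifidobacterium-like Actinobacteria bloom whose rise drives between-infant
# convergence over a known window, and one twin pair with near-identical
# latent dynamics.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

#' Simulation configuration
#'
#' Defaults reproduce the cohort structure assumed throughout: 12 infants,
#' near-daily sampling of the first year (inclusion probability 0.65, about
#' 225 samples per infant), log-normal library sizes with mean 1642 and
#' s.d. 544 (the field-typical 164,215 +/- 54,438 read depth scaled down by
#' 100 for fast runs), four dominant phyla at mean fractions
#' 32.3/16.1/35.4/15.5 percent (renormalized to sum to 1), a planted
#' Actinobacteria bloom whose rise is centered on day 95 with half-width 35
#' (so the induced convergence window is about days 60-130), Dirichlet
#' multinomial counts with concentration 200, one late starter whose sampling
#' begins on day 54, and a twin pair (infants 10 and 11) sharing latent
#' dynamics up to noise.
#'
#' @param n_infants number of infants.
#' @param n_otus number of OTUs.
#' @param day_range_first integer range the first sampled day is drawn from.
#' @param day_range_last integer range the last sampled day is drawn from.
#' @param sampling_rate per-day probability that a day within an infant's
#'   range is sampled.
#' @param library_size_log_mean,library_size_log_sd log-normal parameters of
#'   per-sample library size.
#' @param phylum_base_fractions named 4-vector of mean phylum fractions; must
#'   sum to 1 (within 1e-9).
#' @param bloom_center_day,bloom_half_width,bloom_peak_boost the planted
#'   bloom: its log-abundance boost rises sigmoidally (normal CDF, scale
#'   `bloom_half_width/2`) centered on `bloom_center_day`, then decays slowly
#'   after `bloom_center_day + bloom_half_width`, so the induced convergence
#'   window is approximately `bloom_center_day +/- bloom_half_width`.
#' @param overdispersion Dirichlet concentration of the count model.
#' @param individuality_sd step scale of the per-infant random-walk
#'   trajectory offsets (log scale, per 30-day knot).
#' @param maturation_sd scale of the cohort-common directional maturation
#'   drift (per-OTU log-abundance change from day 1 to day 365). Shared by
#'   all infants, it moves every trajectory steadily through community space
#'   with age (the common time signal) while cancelling out of
#'   contemporaneous between-infant distances.
#' @param maturation_individual_sd scale of each infant's own deviation from
#'   the common maturation drift.
#' @param otu_spread_sd between-OTU log-abundance spread within a phylum.
#' @param cohort_convergence fraction by which the amplitude of individual
#'   offsets shrinks from day 1 to day 365 (cohort-wide slow convergence).
#' @param twin_pair indices of the two twin infants, or `NULL`.
#' @param coupling_noise_sd scale of the independent noise separating the
#'   twins' otherwise shared latent draw.
#' @param late_starter index of the infant whose sampling starts at
#'   `late_start_day` (0 for none).
#' @param late_start_day first sampled day for the late starter.
#' @param knot_spacing days between random-walk knots.
#' @param seed default RNG seed used by the generator functions.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_infants = 12L,
                       n_otus = 150L,
                       day_range_first = c(1L, 9L),
                       day_range_last = c(355L, 365L),
                       sampling_rate = 0.65,
                       library_size_log_mean = log(1642.15) - 0.3229^2 / 2,
                       library_size_log_sd = 0.3229,
                       phylum_base_fractions = c(
                         Bacteroidetes = 0.323, Actinobacteria = 0.161,
                         Firmicutes = 0.354, Proteobacteria = 0.155) / 0.993,
                       bloom_center_day = 95,
                       bloom_half_width = 35,
                       bloom_peak_boost = 4,
                       overdispersion = 200,
                       individuality_sd = 1,
                       maturation_sd = 2,
                       maturation_individual_sd = 1,
                       otu_spread_sd = 1.5,
                       cohort_convergence = 0.75,
                       twin_pair = c(10L, 11L),
                       coupling_noise_sd = 0.15,
                       late_starter = 8L,
                       late_start_day = 54L,
                       knot_spacing = 30L,
                       seed = 1L) {
  cfg <- list(n_infants = as.integer(n_infants), n_otus = as.integer(n_otus),
              day_range_first = as.integer(day_range_first),
              day_range_last = as.integer(day_range_last),
              sampling_rate = sampling_rate,
              library_size_log_mean = library_size_log_mean,
              library_size_log_sd = library_size_log_sd,
              phylum_base_fractions = phylum_base_fractions,
              bloom_center_day = bloom_center_day,
              bloom_half_width = bloom_half_width,
              bloom_peak_boost = bloom_peak_boost,
              overdispersion = overdispersion,
              individuality_sd = individuality_sd,
              maturation_sd = maturation_sd,
              maturation_individual_sd = maturation_individual_sd,
              otu_spread_sd = otu_spread_sd,
              cohort_convergence = cohort_convergence,
              twin_pair = if (!is.null(twin_pair)) as.integer(twin_pair),
              coupling_noise_sd = coupling_noise_sd,
              late_starter = as.integer(late_starter),
              late_start_day = as.integer(late_start_day),
              knot_spacing = as.integer(knot_spacing),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Strong-trend simulation configuration
#'
#' A [sim_config()] variant in which directional maturation dominates every
#' other source of within-infant variation (large common drift, subdued
#' wiggle, mild bloom, low count noise). Under these conditions the leading
#' ordination axis of each infant's samples tracks age, the regime in which
#' per-infant axis-1-versus-day regressions are expected to approach the
#' strong fits reported for real cohorts.
#'
#' @param ... overrides passed on to [sim_config()].
#' @export
strong_trend_config <- function(...) {
  sim_config(maturation_sd = 6, individuality_sd = 0.3,
             bloom_peak_boost = 1.5, overdispersion = 1000, ...)
}

validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$phylum_base_fractions) - 1) > 1e-9) {
    stop("phylum_base_fractions must sum to 1")
  }
  if (any(cfg$phylum_base_fractions <= 0)) stop("phylum fractions must be > 0")
  for (nm in c("sampling_rate", "overdispersion", "individuality_sd",
               "otu_spread_sd", "library_size_log_sd")) {
    if (cfg[[nm]] < 0) stop(nm, " must be non-negative")
  }
  if (cfg$n_otus < length(cfg$phylum_base_fractions)) {
    stop("need at least one OTU per phylum")
  }
  lo <- cfg$bloom_center_day - cfg$bloom_half_width
  hi <- cfg$bloom_center_day + cfg$bloom_half_width
  if (lo < min(cfg$day_range_first) || hi > max(cfg$day_range_last)) {
    stop("bloom window [", lo, ", ", hi, "] must lie inside the day range")
  }
  if (!is.null(cfg$twin_pair) &&
      (length(cfg$twin_pair) != 2L || any(cfg$twin_pair > cfg$n_infants))) {
    stop("twin_pair must index two infants")
  }
  invisible(cfg)
}

# Time course of the planted bloom's log-abundance boost (0..peak_boost).
# Sigmoidal rise centered on center_day (scale half_width/2), then a slow
# Gaussian decay starting at center_day + half_width, so the cohort-wide
# distance descent occupies approximately center_day +/- half_width and a
# divergence phase follows.
bloom_boost <- function(day, center, half_width, peak) {
  rise <- stats::pnorm((day - center) / (half_width / 2))
  over <- pmax(0, day - (center + half_width))
  peak * rise * exp(-over^2 / (2 * half_width^2))
}

#' Generate a random phylum-structured phylogeny over OTUs
#'
#' OTUs sharing a phylum form clades: a random coalescent subtree is grown per
#' phylum and the subtrees are grafted onto a random binary backbone with
#' exponential branch lengths, so phylum-level signal is visible to UniFrac.
#'
#' @param n_otus number of OTUs (>= 2).
#' @param taxonomy data.frame with columns `otu_id` and `phylum`.
#' @param seed RNG seed.
#' @return a rooted binary `ape::phylo` with `n_otus` leaves.
#' @export
generate_tree <- function(n_otus, taxonomy, seed = 1L) {
  if (n_otus < 2L) stop("n_otus must be >= 2")
  if (!all(c("otu_id", "phylum") %in% names(taxonomy))) {
    stop("taxonomy must have otu_id and phylum columns")
  }
  with_seed(seed, {
    groups <- split(as.character(taxonomy$otu_id), taxonomy$phylum)
    subtrees <- lapply(groups, function(tips) {
      if (length(tips) == 1L) {
        sprintf("%s:%.6f", tips, rexp(1, rate = 5))
      } else {
        tr <- ape::rcoal(length(tips), tip.label = tips)
        s <- ape::write.tree(tr)
        sub("\\);$", sprintf("):%.6f", rexp(1, rate = 5)), s)
      }
    })
    # random sequential binary joins of the phylum subtrees
    pool <- unname(subtrees)
    while (length(pool) > 1L) {
      pick <- sample.int(length(pool), 2L)
      joined <- sprintf("(%s,%s):%.6f", pool[[pick[1L]]], pool[[pick[2L]]],
                        rexp(1, rate = 5))
      pool <- c(pool[-pick], list(joined))
    }
    nwk <- sub(":[0-9.]+$", ";", pool[[1L]])
    ape::read.tree(text = nwk)
  })
}

#' Generate latent per-infant compositional trajectories
#'
#' Per infant and OTU, smooth log-abundance = phylum/OTU baseline +
#' autocorrelated per-infant random-walk offset (knots every `knot_spacing`
#' days, cubic-spline interpolated, amplitude shrinking with age by
#' `cohort_convergence`) + the planted bloom boost on the designated
#' Actinobacteria OTU; each day's composition is the softmax of the
#' log-abundances, so the bloom compositionally depresses all other taxa
#' inside its window. The twin pair shares one random-walk draw plus
#' independent knot noise of scale `coupling_noise_sd`.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return a list of class `latent_trajectories`: `compositions` (per infant, a
#'   365 x n_otus daily composition matrix), `taxonomy`, `bloom_otu`,
#'   `window` (ground-truth convergence window), `days`.
#' @export
generate_latent <- function(config, seed = config$seed) {
  validate_sim_config(config)
  with_seed(seed, {
    n_inf <- config$n_infants
    n_otu <- config$n_otus
    phyla <- names(config$phylum_base_fractions)
    days <- seq_len(365L)

    # OTU identities: phylum assignment round-robin by expected fraction,
    # within-phylum abundance spread shared by all infants
    n_per <- pmax(round(config$phylum_base_fractions * n_otu), 1)
    while (sum(n_per) > n_otu) n_per[which.max(n_per)] <- n_per[which.max(n_per)] - 1L
    while (sum(n_per) < n_otu) n_per[which.min(n_per)] <- n_per[which.min(n_per)] + 1L
    otu_phylum <- rep(phyla, n_per)
    otu_ids <- sprintf("OTU%d", seq_len(n_otu))
    base <- log(config$phylum_base_fractions[otu_phylum] / n_per[otu_phylum]) +
      rnorm(n_otu, 0, config$otu_spread_sd)
    names(base) <- otu_ids

    act <- which(otu_phylum == "Actinobacteria")
    bloom_otu <- otu_ids[act[which.max(base[act])]]
    # the bloom taxon is the cohort's top OTU overall (a Bifidobacterium-like
    # dominant), so its baseline matches the largest draw
    base[bloom_otu] <- max(base)
    boost <- bloom_boost(days, config$bloom_center_day,
                         config$bloom_half_width, config$bloom_peak_boost)

    knots <- unique(c(seq(1L, 365L, by = config$knot_spacing), 365L))
    # individuality amplitude: pioneer communities start similar (ramp over
    # the first ~2 months), then slow cohort-wide convergence with age
    ramp <- pmin(1, 0.5 + 0.5 * days / 60)
    envelope <- ramp * (1 - config$cohort_convergence * (days - 1) / 364)

    rw <- function(sd) {
      # standardized random walk over knots: autocorrelated drift with
      # constant marginal sd, so the age envelope controls net convergence
      w <- apply(matrix(rnorm(length(knots) * n_otu), length(knots)), 2L,
                 cumsum)
      sd * w / sqrt(seq_along(knots))
    }
    smooth_offsets <- function(kn_vals) {
      apply(kn_vals, 2L, function(v) {
        spline(knots, v, xout = days, method = "fmm")$y
      })
    }

    twin <- config$twin_pair
    shared_twin <- if (!is.null(twin)) rw(config$individuality_sd)
    shared_twin_drift <- if (!is.null(twin)) {
      rnorm(n_otu, 0, config$maturation_individual_sd)
    }
    age <- (days - 1) / 364
    common_drift <- rnorm(n_otu, 0, config$maturation_sd)
    comps <- vector("list", n_inf)
    for (i in seq_len(n_inf)) {
      if (!is.null(twin) && i %in% twin) {
        kn <- shared_twin +
          matrix(rnorm(length(knots) * n_otu, 0, config$coupling_noise_sd),
                 length(knots))
        drift <- shared_twin_drift
      } else {
        kn <- rw(config$individuality_sd)
        drift <- rnorm(n_otu, 0, config$maturation_individual_sd)
      }
      # enveloped stationary wiggle + individual drift, plus the cohort's
      # common maturation drift (shared, so it cancels between infants)
      offs <- (smooth_offsets(kn) + outer(age, drift)) * envelope +
        outer(age, common_drift)
      loga <- sweep(offs, 2L, base, "+")
      loga[, otu_ids == bloom_otu] <- loga[, otu_ids == bloom_otu] + boost
      w <- exp(loga - apply(loga, 1L, max))
      comp <- w / rowSums(w)
      dimnames(comp) <- list(NULL, otu_ids)
      comps[[i]] <- comp
    }
    infant_ids <- sprintf("ID%d", seq_len(n_inf))
    names(comps) <- infant_ids

    taxonomy <- data.frame(
      otu_id = otu_ids,
      domain = "Bacteria",
      phylum = otu_phylum,
      class = "unclassified", order = "unclassified",
      family = "unclassified",
      genus = ifelse(otu_ids == bloom_otu, "Bifidobacterium", "unclassified"),
      stringsAsFactors = FALSE)

    structure(list(compositions = comps, taxonomy = taxonomy,
                   bloom_otu = bloom_otu,
                   window = c(config$bloom_center_day - config$bloom_half_width,
                              config$bloom_center_day + config$bloom_half_width),
                   days = days, config = config),
              class = "latent_trajectories")
  })
}

#' Sample an observed count table from latent trajectories
#'
#' Sampled days are drawn per infant by independent inclusion at
#' `sampling_rate` within that infant's day range (first/last days drawn from
#' the configured ranges; the designated late starter begins at
#' `late_start_day`). Library sizes are log-normal; counts are
#' Dirichlet-multinomial around the latent composition with the configured
#' concentration.
#'
#' @param latent a [generate_latent()] result.
#' @param config a [sim_config()] (defaults to the one inside `latent`).
#' @param seed RNG seed.
#' @return a list of class `gut_cohort` with `counts`, `taxonomy`, `meta`,
#'   `tree = NULL`, and a `truth` element holding the latent ground truth.
#' @export
sample_counts <- function(latent, config = latent$config,
                          seed = config$seed + 1L) {
  validate_sim_config(config)
  with_seed(seed, {
    n_inf <- config$n_infants
    infant_ids <- names(latent$compositions)
    rows <- list(); meta_rows <- list()
    for (i in seq_len(n_inf)) {
      pick <- function(rng) {
        span <- seq(rng[1L], rng[2L])
        if (length(span) == 1L) span else sample(span, 1L)
      }
      first <- if (i == config$late_starter) {
        config$late_start_day
      } else {
        pick(config$day_range_first)
      }
      last <- pick(config$day_range_last)
      span <- seq(first, last)
      sampled <- integer(0)
      for (try in seq_len(10L)) {
        keep <- rbinom(length(span), 1L, config$sampling_rate) == 1L
        sampled <- span[keep]
        if (length(sampled) > 0L) break
        warning("infant ", infant_ids[i],
                ": no sampled days, regenerating (try ", try, ")")
      }
      if (length(sampled) == 0L) {
        stop("infant ", infant_ids[i], ": no sampled days after 10 tries")
      }
      lib <- pmax(1L, round(rlnorm(length(sampled),
                                   config$library_size_log_mean,
                                   config$library_size_log_sd)))
      comp <- latent$compositions[[i]]
      cnt <- matrix(0L, length(sampled), ncol(comp))
      for (s in seq_along(sampled)) {
        p <- comp[sampled[s], ]
        if (is.finite(config$overdispersion)) {
          g <- rgamma(length(p), shape = config$overdispersion * p)
          if (sum(g) == 0) g <- p
          p <- g / sum(g)
        }
        cnt[s, ] <- rmultinom(1L, lib[s], p)[, 1L]
      }
      rownames(cnt) <- sprintf("%s_d%03d", infant_ids[i], sampled)
      rows[[i]] <- cnt
      meta_rows[[i]] <- data.frame(sample_id = rownames(cnt),
                                   infant_id = infant_ids[i],
                                   day_since_birth = sampled,
                                   preservation = "frozen",
                                   stringsAsFactors = FALSE)
    }
    counts <- do.call(rbind, rows)
    colnames(counts) <- colnames(latent$compositions[[1L]])
    meta <- do.call(rbind, meta_rows)
    # drop all-zero rows (possible at tiny library sizes)
    keep <- rowSums(counts) > 0L
    counts <- counts[keep, , drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
    ch <- validate_cohort(counts, latent$taxonomy, meta, tree = NULL)
    ch$truth <- list(
      bloom_otu = latent$bloom_otu,
      window = latent$window,
      twin_pair = if (!is.null(config$twin_pair))
        infant_ids[config$twin_pair],
      late_starter = if (config$late_starter > 0L)
        infant_ids[config$late_starter],
      scalars = list(bloom_otu = latent$bloom_otu,
                     window_start = latent$window[1L],
                     window_end = latent$window[2L]))
    ch$latent <- latent
    ch
  })
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper: [generate_latent()], [sample_counts()], and
#' [generate_tree()] with seeds derived from one master seed. Identical
#' config + seed give byte-identical output.
#'
#' @param config a [sim_config()].
#' @param seed master RNG seed (defaults to `config$seed`).
#' @return a `gut_cohort` with `truth` and `latent` attached.
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed) {
  latent <- generate_latent(config, seed = seed)
  ch <- sample_counts(latent, config, seed = seed + 1L)
  ch$tree <- generate_tree(config$n_otus, latent$taxonomy, seed = seed + 2L)
  ch
}
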