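#' Simulate taxon ranges by a discrete-bin birth-death process
#'
#' Bins are treated as unit time intervals. Every taxon alive in bin i goes
#' extinct within it with probability `1 - exp(-mu_i)`, so `mu_i` is the
#' per-taxon, per-interval extinction rate. New taxa arise in bin i as
#' `Poisson(S_i * (exp(lambda_i) - 1))`, where `S_i` is the standing
#' diversity entering the bin: the `exp(lambda) - 1` form makes `lambda_i`
#' the per-capita, per-interval origination rate as measured by
#' boundary-crosser and three-timer estimators (the fraction of top-boundary
#' crossers that originated within the bin is `1 - exp(-lambda)` in
#' expectation). Origination and extinction times are drawn uniformly within
#' their bins; newborns take their survival draw for the full bin. Taxa
#' alive at the end of the scheme are censored at its younger bound. Total
#' extinction is permitted: later bins may be empty.
#'
#' @param n0 Initial number of taxa (originating at the scheme's older
#'   bound).
#' @param scheme A [bin_scheme].
#' @param mu,lambda Per-interval extinction and origination rates, scalars
#'   or per-bin vectors.
#' @param seed Integer seed; the run is reproducible from `(args, seed)`.
#' @return A `sim_truth` list: `taxa` (data.frame `taxon`, `orig_bin`,
#'   `orig_age`, `ext_bin`, `ext_age`, `censored`), `richness` (per-bin
#'   standing richness), `entering` (taxa alive at each bin's older
#'   boundary), `scheme`, `mu`, `lambda`, `seed`.
#' @export
simulate_ranges <- function(n0, scheme, mu, lambda, seed = NULL) {
  stopifnot(inherits(scheme, "bin_scheme"), n0 >= 0)
  nb <- nrow(scheme)
  mu <- rep_len(as.numeric(mu), nb)
  lambda <- rep_len(as.numeric(lambda), nb)
  if (any(mu < 0) || any(lambda < 0)) stop("rates must be >= 0")
  with_seed(seed, {
    orig_bin <- rep(1L, n0)
    orig_age <- rep(scheme$older[1L], n0)
    ext_bin <- rep(NA_integer_, n0)
    ext_age <- rep(NA_real_, n0)
    alive <- seq_len(n0)
    entering <- integer(nb)
    for (i in seq_len(nb)) {
      entering[i] <- length(alive)
      n_new <- if (length(alive)) stats::rpois(1L, length(alive) * expm1(lambda[i])) else 0L
      if (n_new > 0L) {
        new_ids <- length(orig_bin) + seq_len(n_new)
        orig_bin <- c(orig_bin, rep(i, n_new))
        orig_age <- c(orig_age, stats::runif(n_new, scheme$younger[i], scheme$older[i]))
        ext_bin <- c(ext_bin, rep(NA_integer_, n_new))
        ext_age <- c(ext_age, rep(NA_real_, n_new))
        alive <- c(alive, new_ids)
      }
      if (length(alive)) {
        dies <- stats::runif(length(alive)) < 1 - exp(-mu[i])
        dead <- alive[dies]
        if (length(dead)) {
          ext_bin[dead] <- i
          ext_age[dead] <- stats::runif(length(dead), scheme$younger[i],
                                        pmin(orig_age[dead], scheme$older[i]))
          alive <- alive[!dies]
        }
      }
    }
    censored <- is.na(ext_bin)
    ext_bin[censored] <- nb
    ext_age[censored] <- scheme$younger[nb]
    n <- length(orig_bin)
    taxa <- data.frame(
      taxon = sprintf("g%05d", seq_len(n)),
      orig_bin = orig_bin, orig_age = orig_age,
      ext_bin = ext_bin, ext_age = ext_age, censored = censored,
      stringsAsFactors = FALSE
    )
    richness <- vapply(seq_len(nb), function(i) {
      sum(orig_bin <= i & ext_bin >= i)
    }, integer(1L))
    structure(list(taxa = taxa, richness = richness, entering = entering,
                   scheme = scheme, mu = mu, lambda = lambda, seed = seed),
              class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Simulated truth: %d taxa over %d bins (richness %d-%d)\n",
              nrow(x$taxa), nrow(x$scheme), min(x$richness), max(x$richness)))
  invisible(x)
}

#' Simulate a fossil occurrence table from known ranges
#'
#' For each taxon and each bin of its true range, the number of occurrences
#' is `Poisson(r_i * a_ij)`, where `r_i` sets the (heavily uneven, if
#' desired) per-bin sampling intensity and `a_ij` is a per-taxon, per-bin
#' relative abundance drawn from a lognormal with log-sd `abundance_sdlog`
#' and mean 1 — the skewed taxon abundance distribution that
#' coverage-standardised subsampling exists to handle. Abundances are
#' redrawn per bin because a genus's relative abundance is not expected to
#' persist over multi-Myr intervals. Set `abundance_sdlog = 0` for
#' homogeneous taxa, in which case the per-bin detection probability of a
#' living taxon is `1 - exp(-r_i)`. Occurrence
#' ages are drawn uniformly within the overlap of the bin and the taxon's
#' range, then resolved to an age range `age +- age_smear` Myr (clipped to
#' the scheme span): with `age_smear = 0` every occurrence is single-bin,
#' while positive smear makes occurrences near boundaries straddle bins,
#' feeding the unconstrained binning policy. Occurrences are clustered into
#' collections with lognormally skewed sizes, and collections into
#' publications. The number of collections per bin scales with the
#' occurrence count (`ceiling(O / collection_size)`), as in real occurrence
#' databases where better-sampled intervals yield more, not larger,
#' collections.
#'
#' @param truth A `sim_truth` from [simulate_ranges()].
#' @param r Per-bin sampling intensity (scalar or vector).
#' @param collection_size Mean occurrences per collection (default 2.5).
#' @param colls_per_pub Mean collections per publication (default 4).
#' @param abundance_sdlog Log-sd of the per-taxon relative abundance
#'   multipliers (default 1.5).
#' @param age_smear Half-width (Myr) added to each occurrence's age range.
#' @param seed Integer seed.
#' @param realm Realm tag for all rows.
#' @param continent_probs Named probabilities for the continent tag.
#' @return An [occurrence_table]; the generating bin of each occurrence is
#'   attached as attribute `gen_bin`.
#' @export
simulate_occurrences <- function(truth, r, collection_size = 2.5,
                                 colls_per_pub = 4, abundance_sdlog = 1.5,
                                 age_smear = 0, seed = NULL, realm = "nonmarine",
                                 continent_probs = c(Europe = 0.4, Asia = 0.2,
                                                     Africa = 0.1, SouthAmerica = 0.1,
                                                     NorthAmerica = 0.15, Other = 0.05)) {
  stopifnot(inherits(truth, "sim_truth"))
  scheme <- truth$scheme
  nb <- nrow(scheme)
  r <- rep_len(as.numeric(r), nb)
  with_seed(seed, {
    rows <- list()
    gen_bin <- integer(0)
    tx <- truth$taxa
    for (i in seq_len(nb)) {
      present <- which(tx$orig_bin <= i & tx$ext_bin >= i)
      if (!length(present) || r[i] <= 0) next
      abund <- if (abundance_sdlog > 0) {
        stats::rlnorm(length(present), -abundance_sdlog^2 / 2, abundance_sdlog)
      } else rep(1, length(present))
      counts <- stats::rpois(length(present), r[i] * abund)
      tot <- sum(counts)
      if (tot == 0L) next
      n_coll <- max(2L, ceiling(tot / collection_size))
      n_pub <- max(2L, ceiling(n_coll / colls_per_pub))
      coll_w <- stats::rlnorm(n_coll)
      coll_idx <- sample.int(n_coll, tot, replace = TRUE,
                             prob = coll_w / sum(coll_w))
      pub_of_coll <- sample.int(n_pub, n_coll, replace = TRUE,
                                prob = { w <- stats::rlnorm(n_pub); w / sum(w) })
      who <- rep(present, counts)
      lo <- pmax(scheme$younger[i], tx$ext_age[who])
      hi <- pmin(scheme$older[i], tx$orig_age[who])
      age <- stats::runif(tot, lo, pmax(lo, hi))
      rows[[i]] <- data.frame(
        genus = tx$taxon[who],
        collection_id = sprintf("c%02d_%04d", i, coll_idx),
        publication_id = sprintf("p%02d_%04d", i, pub_of_coll[coll_idx]),
        age_max = pmin(age + age_smear, scheme$older[1L]),
        age_min = pmax(age - age_smear, scheme$younger[nb]),
        stringsAsFactors = FALSE
      )
      gen_bin <- c(gen_bin, rep(i, tot))
    }
    if (!length(rows)) {
      df <- data.frame(occurrence_id = character(0), taxon = character(0),
                       genus = character(0), species = character(0),
                       collection_id = character(0), publication_id = character(0),
                       age_max = numeric(0), age_min = numeric(0),
                       realm = character(0), continent = character(0),
                       stringsAsFactors = FALSE)
      out <- structure(df, class = c("occurrence_table", "data.frame"))
      attr(out, "gen_bin") <- integer(0)
      return(out)
    }
    df <- do.call(rbind, rows)
    df$occurrence_id <- sprintf("o%06d", seq_len(nrow(df)))
    df$species <- ""
    df$realm <- realm
    df$continent <- sample(names(continent_probs), nrow(df), replace = TRUE,
                           prob = continent_probs)
    out <- occurrence_table(df)
    attr(out, "gen_bin") <- gen_bin
    out
  })
}

#' Simulate a tree consistent with origination order
#'
#' Taxa are added in order of true origination (ties shuffled); each new
#' taxon buds as sister to a uniformly chosen already-present taxon, so no
#' lineage ever branches from one that originates later. A stated fraction
#' of internal nodes can then be collapsed into polytomies to exercise the
#' resolution policies.
#'
#' @param truth A `sim_truth`.
#' @param polytomy_fraction Probability that each internal (non-root) node
#'   is collapsed into its parent.
#' @param seed Integer seed.
#' @return List with `tree` (an `ape::phylo`), `fads`, `lads` (named by
#'   taxon; origination and extinction ages in Ma).
#' @export
simulate_tree <- function(truth, polytomy_fraction = 0, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  tx <- truth$taxa
  if (nrow(tx) < 2L) stop("need at least 2 taxa to build a tree")
  with_seed(seed, {
    ord <- order(-tx$orig_age, stats::runif(nrow(tx)))
    labs <- tx$taxon[ord]
    s <- sprintf("(%s,%s)", labs[1L], labs[2L])
    for (j in seq_len(nrow(tx))[-(1:2)]) {
      host <- labs[sample.int(j - 1L, 1L)]
      s <- sub(host, sprintf("(%s,%s)", host, labs[j]), s, fixed = TRUE)
    }
    tree <- ape::read.tree(text = paste0(s, ";"))
    if (polytomy_fraction > 0) {
      # returns a list of subtrees: length > 1 means the node was collapsed
      # and its children splice into the parent; the root never collapses away
      rec <- function(z) {
        if (is.character(z)) return(list(z))
        kids <- list()
        for (c_el in z) kids <- c(kids, rec(c_el))
        if (stats::runif(1L) < polytomy_fraction) return(kids)
        list(kids)
      }
      res <- rec(phylo_to_nested(tree))
      root <- if (length(res) == 1L) res[[1L]] else res
      tree <- ape::read.tree(text = nested_to_newick(root))
    }
    list(tree = tree,
         fads = stats::setNames(tx$orig_age, tx$taxon)[tree$tip.label],
         lads = stats::setNames(tx$ext_age, tx$taxon)[tree$tip.label])
  })
}

#' Simulate a diversity response driven by one covariate
#'
#' `y_t = beta * e_t + u_t`, where `e_t` are the driver's AR1 residuals and
#' `u_t` is an AR1(`phi`, `sigma`) noise process started from its stationary
#' distribution. Used to verify that the model-comparison machinery
#' recovers a known driver against decoys.
#'
#' @param driver Numeric covariate series (per bin, old to young).
#' @param beta Driver effect size.
#' @param phi,sigma Noise autocorrelation and innovation sd.
#' @param seed Integer seed.
#' @return Numeric response series (NA in the first bin when `beta != 0`,
#'   where the driver residual is undefined).
#' @export
simulate_driver_response <- function(driver, beta, phi = 0.3, sigma = 0.3,
                                     seed = NULL) {
  n <- length(driver)
  with_seed(seed, {
    u <- numeric(n)
    if (sigma > 0) {
      u[1L] <- stats::rnorm(1L, 0, if (abs(phi) < 1) sigma / sqrt(1 - phi^2) else sigma)
      for (t in 2:n) u[t] <- phi * u[t - 1L] + stats::rnorm(1L, 0, sigma)
    }
    if (beta == 0) return(u)
    e <- ar1_residuals(as.numeric(driver))$residuals
    beta * e + u
  })
}

#' The built-in J/K-like simulation scenario
#'
#' A 14-bin scenario shaped like the Jurassic/Cretaceous transition it is
#' meant to exercise: a modest origination-led richness ramp through the
#' later Jurassic bins (J4-J6), a single high-extinction bin at the end of
#' the Jurassic (J6), suppressed origination through the earliest Cretaceous
#' (K1-K3), heavily uneven background sampling, and a five-fold sampling
#' drop in the two bins after the event (K1-K2 at a fifth of the J6
#' intensity) — the combination that makes raw counts misleading and the
#' coverage-standardised estimate informative. Per-taxon abundances are
#' lognormally skewed. Sampling intensities are set high enough that even
#' the degraded post-event bins usually retain coverage above the baseline
#' quorum of 0.4: the scenario's purpose is to compare estimators where
#' both are defined (zero-coverage intervals, which do occur in real data,
#' are exercised by dedicated degenerate-input tests instead).
#'
#' @param n0 Initial taxa (default 200).
#' @return A scenario list understood by [simulate_scenario()]: `scheme`,
#'   `n0`, `mu`, `lambda`, `r`, `collection_size`, `colls_per_pub`,
#'   `abundance_sdlog`, `age_smear`, `realm`.
#' @export
jk_scenario <- function(n0 = 200L) {
  scheme <- tenmyr_bins()
  nb <- nrow(scheme)
  mu <- rep(0.15, nb); mu[6L] <- 0.8
  lambda <- rep(0.15, nb); lambda[4:6] <- 0.25; lambda[7:9] <- 0.05
  r <- c(1.5, 8, 1.2, 12, 2.5, 15, 3, 3, 6, 1.2, 10, 2, 8, 2.5)
  list(scheme = scheme, n0 = as.integer(n0), mu = mu, lambda = lambda, r = r,
       collection_size = 2.5, colls_per_pub = 4, abundance_sdlog = 1.5,
       age_smear = 0, realm = "nonmarine")
}

#' Run a full synthetic scenario
#'
#' Generates ranges, occurrences and a tree from one scenario and seed.
#' Sub-stage seeds are derived from the master seed, so the pieces are
#' individually reproducible.
#'
#' @param scenario A scenario list (see [jk_scenario()]).
#' @param seed Master integer seed.
#' @return List with `truth`, `occurrences`, `tree`, `fads`, `lads`,
#'   `scenario`, `seed`.
#' @export
simulate_scenario <- function(scenario = jk_scenario(), seed = 1L) {
  truth <- simulate_ranges(scenario$n0, scenario$scheme, scenario$mu,
                           scenario$lambda, seed = stage_seed(seed, "ranges"))
  occ <- simulate_occurrences(truth, scenario$r,
                              collection_size = scenario$collection_size %||% 2.5,
                              colls_per_pub = scenario$colls_per_pub %||% 4,
                              abundance_sdlog = scenario$abundance_sdlog %||% 1.5,
                              age_smear = scenario$age_smear %||% 0,
                              seed = stage_seed(seed, "occurrences"),
                              realm = scenario$realm %||% "nonmarine")
  tr <- if (nrow(truth$taxa) >= 2L) {
    simulate_tree(truth, polytomy_fraction = scenario$polytomy_fraction %||% 0,
                  seed = stage_seed(seed, "tree"))
  } else NULL
  list(truth = truth, occurrences = occ, tree = tr$tree, fads = tr$fads,
       lads = tr$lads, scenario = scenario, seed = seed)
}
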