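#' Good's u coverage estimator
#'
#' Coverage of a bin's frequency distribution: `u = 1 - s1/O`, where `s1` is
#' the number of singleton taxa (taxa with exactly one occurrence in the bin)
#' and `O` the total occurrence count. With `correct_dominant = TRUE` the
#' occurrences of the single most frequent taxon are removed from the
#' denominator (`u = 1 - s1/(O - n_dominant)`), compensating for the
#' distortion a very abundant taxon exerts on the frequency distribution.
#' The result is clamped to `[0, 1]`; a bin whose taxa are all singletons has
#' zero coverage.
#'
#' @param counts Per-taxon occurrence counts within one bin (values >= 1),
#'   optionally named by taxon.
#' @param correct_dominant Remove the dominant taxon's occurrences from the
#'   denominator.
#' @return Coverage in `[0, 1]`, or `NA` when the bin is empty.
#' @examples
#' goods_u(c(3, 2, 1, 1)) # 5/7
#' @export
goods_u <- function(counts, correct_dominant = FALSE) {
  counts <- counts[!is.na(counts)]
  O <- sum(counts)
  if (length(counts) == 0L || O == 0) return(NA_real_)
  if (any(counts < 1)) stop("per-taxon counts must be >= 1")
  s1 <- sum(counts == 1)
  denom <- if (correct_dominant) O - max(counts) else O
  if (denom <= 0) return(if (s1 > 0) 0 else 1)
  min(1, max(0, 1 - s1 / denom))
}

#' Configuration for shareholder quorum subsampling
#'
#' Two dialects are provided. `"throttled"` draws whole collections in random
#' order but throttles publication pressure: once a collection from a new
#' publication is drawn, further collections from that publication are drawn
#' until exactly `pubs_cap` of them have been selected (or the publication is
#' exhausted), and publications already at the cap contribute no further
#' collections. `"plain"` draws collections in unrestricted random order.
#' The dialects coincide whenever no publication contributes more than
#' `pubs_cap` collections to a bin.
#'
#' @param quorum Target coverage quorum in (0, 1]; default 0.4.
#' @param trials Subsampling trials per replicate (default 1000).
#' @param replicates Number of replicates; per-replicate means are retained
#'   when > 1. Defaults to 1 for the throttled dialect and 100 for plain.
#' @param dialect `"throttled"` or `"plain"`.
#' @param pubs_cap Collections drawn per publication under throttling.
#' @param exclude_singletons Do not count in-bin singleton taxa toward the
#'   subsampled richness tally.
#' @param include_dominant Count the dominant taxon in the tally whenever it
#'   is drawn (default TRUE).
#' @param dominant_share Credit the dominant taxon's frequency share toward
#'   the quorum. Default FALSE, following the published algorithm: the most
#'   common taxon's frequency is withheld from the coverage accumulation
#'   (and the remaining taxa's shares are taken relative to the non-dominant
#'   occurrence total), because a very abundant taxon would otherwise
#'   satisfy the quorum on its own and truncate the subsample.
#' @param correct_dominant Use the dominant-corrected form of Good's u for
#'   the coverage estimate (default TRUE, consistent with withholding the
#'   dominant's share).
#' @param seed Integer seed; seeded runs are bit-reproducible.
#' @return An `sqs_config` list.
#' @export
sqs_config <- function(quorum = 0.4, trials = 1000L, replicates = NULL,
                       dialect = c("throttled", "plain"), pubs_cap = 3L,
                       exclude_singletons = TRUE, include_dominant = TRUE,
                       dominant_share = FALSE, correct_dominant = TRUE,
                       seed = NULL) {
  dialect <- match.arg(dialect)
  if (!(quorum > 0 && quorum <= 1)) stop("quorum must be in (0, 1]")
  if (trials < 1) stop("trials must be positive")
  if (is.null(replicates)) replicates <- if (dialect == "plain") 100L else 1L
  structure(list(quorum = quorum, trials = as.integer(trials),
                 replicates = as.integer(replicates), dialect = dialect,
                 pubs_cap = as.integer(pubs_cap),
                 exclude_singletons = isTRUE(exclude_singletons),
                 include_dominant = isTRUE(include_dominant),
                 dominant_share = isTRUE(dominant_share),
                 correct_dominant = isTRUE(correct_dominant), seed = seed),
            class = "sqs_config")
}

# Precompute the per-bin structures one trial needs: per-taxon counts and
# frequency shares, the dominant taxon, singleton flags, coverage u and the
# u-adjusted quorum target.
sqs_bin_data <- function(taxon, collection_id, publication_id, cfg) {
  counts <- table(taxon)
  O <- sum(counts)
  taxa <- names(counts)
  dominant <- taxa[which.max(counts)]
  # when the dominant's share is withheld, remaining shares are relative to
  # the non-dominant occurrence total, so the accumulable share still sums
  # to one
  denom <- if (cfg$dominant_share) O else O - max(counts)
  share <- if (denom > 0) as.numeric(counts) / denom else rep(0, length(counts))
  names(share) <- taxa
  if (!cfg$dominant_share) share[dominant] <- 0
  singleton <- as.numeric(counts) == 1
  names(singleton) <- taxa
  u <- goods_u(as.numeric(counts), correct_dominant = cfg$correct_dominant)
  colls <- split(taxon, as.character(collection_id))
  colls <- lapply(colls, unique)
  coll_ids <- names(colls)
  pub_of <- vapply(coll_ids, function(cid) {
    as.character(publication_id[match(cid, as.character(collection_id))])
  }, character(1L))
  list(taxa = taxa, share = share, dominant = dominant, singleton = singleton,
       u = u, O = O, colls = colls, coll_ids = coll_ids, pub_of = pub_of,
       richness = length(taxa))
}

# One deterministic subsampling pass given an explicit collection order.
# Accumulates each taxon's frequency share once, on first draw, and stops
# after the collection that lifts the accumulated share past the u-adjusted
# target q/u (so that q is coverage of the true, not the observed, frequency
# distribution). Returns the qualifying distinct-taxon tally.
sqs_draw <- function(bd, cfg, order) {
  target <- cfg$quorum / bd$u
  seen <- new.env(parent = emptyenv())
  acc <- 0
  rich <- 0L
  eps <- 1e-12
  counts_tally <- function(tx) {
    (cfg$include_dominant || tx != bd$dominant) &&
      (!cfg$exclude_singletons || !bd$singleton[[tx]])
  }
  draw_one <- function(cid) {
    for (tx in bd$colls[[cid]]) {
      if (!is.null(seen[[tx]])) next
      seen[[tx]] <- TRUE
      acc <<- acc + bd$share[[tx]]
      if (counts_tally(tx)) rich <<- rich + 1L
    }
  }
  if (cfg$dialect == "plain") {
    for (cid in order) {
      draw_one(cid)
      if (acc >= target - eps) break
    }
  } else {
    drawn <- logical(length(order))
    pubs <- unique(bd$pub_of)
    pub_n <- stats::setNames(integer(length(pubs)), pubs)
    pub_of_order <- bd$pub_of[order]
    pos <- 1L
    repeat {
      # skip collections already drawn or whose publication hit the cap
      while (pos <= length(order) &&
             (drawn[pos] || pub_n[[pub_of_order[pos]]] >= cfg$pubs_cap)) {
        pos <- pos + 1L
      }
      if (pos > length(order)) break
      cid <- order[pos]
      pub <- pub_of_order[pos]
      drawn[pos] <- TRUE
      pub_n[[pub]] <- pub_n[[pub]] + 1L
      draw_one(cid)
      if (acc >= target - eps) break
      # throttle: keep drawing this publication until pubs_cap selected
      while (pub_n[[pub]] < cfg$pubs_cap) {
        nxt <- which(!drawn & pub_of_order == pub)
        if (!length(nxt)) break
        drawn[nxt[1L]] <- TRUE
        pub_n[[pub]] <- pub_n[[pub]] + 1L
        draw_one(order[nxt[1L]])
        if (acc >= target - eps) break
      }
      if (acc >= target - eps) break
    }
  }
  rich
}

#' One shareholder-quorum subsampling trial
#'
#' Draws collections (in random order, or in an explicitly supplied order)
#' until the accumulated coverage share of drawn taxa reaches the u-adjusted
#' quorum, and returns the number of qualifying distinct taxa drawn. Exposed
#' chiefly so small bins can be checked exhaustively against enumeration of
#' all draw orders.
#'
#' @param occs A data.frame with columns `taxon`, `collection_id`,
#'   `publication_id` — the occurrences of a single bin.
#' @param cfg An [sqs_config].
#' @param order Optional explicit collection order (character vector of
#'   collection ids); when `NULL` a uniform random permutation is drawn from
#'   the current RNG stream.
#' @return Integer subsampled richness, or `NA` when the bin's coverage is
#'   below the quorum.
#' @export
sqs_trial <- function(occs, cfg, order = NULL) {
  bd <- sqs_bin_data(occs$taxon, occs$collection_id, occs$publication_id, cfg)
  if (!is.finite(bd$u) || bd$u <= 0 || bd$u < cfg$quorum) return(NA_integer_)
  if (is.null(order)) order <- sample(bd$coll_ids)
  sqs_draw(bd, cfg, order)
}

#' Coverage-standardised (SQS) diversity estimate
#'
#' Runs repeated subsampling trials per bin and reports the mean and
#' standard deviation of subsampled richness, together with each bin's
#' Good's u coverage. Bins whose coverage is undefined (empty), zero (all
#' singletons) or below the quorum return `NA` rather than a downward-biased
#' estimate. Under the unconstrained policy each trial first assigns every
#' multi-bin occurrence to one of its candidate bins uniformly at random, so
#' temporally uncertain occurrences contribute without double counting.
#'
#' @param binned A `binned_occurrences` object (either policy).
#' @param cfg An [sqs_config]. `cfg$seed` makes the run bit-reproducible.
#' @return An `sqs_result` data.frame: `bin`, `midpoint`, `u`, `mean`, `sd`,
#'   `n_trials`, `observed`. When `cfg$replicates > 1` the matrix of
#'   per-replicate means is attached as attribute `replicate_means`.
#' @export
sqs_estimate <- function(binned, cfg = sqs_config()) {
  stopifnot(inherits(binned, "binned_occurrences"))
  scheme <- binned$scheme
  nb <- nrow(scheme)
  total <- cfg$trials * cfg$replicates
  with_seed(cfg$seed, {
    draws <- matrix(NA_real_, nrow = total, ncol = nb)
    u_rec <- matrix(NA_real_, nrow = if (binned$policy == "constrained") 1L else total,
                    ncol = nb)
    observed <- integer(nb)
    if (binned$policy == "constrained") {
      for (b in seq_len(nb)) {
        rows <- binned$table$bin == b
        if (!any(rows)) next
        occs <- binned$table[rows, , drop = FALSE]
        bd <- sqs_bin_data(occs$taxon, occs$collection_id, occs$publication_id, cfg)
        observed[b] <- bd$richness
        u_rec[1L, b] <- bd$u
        if (!is.finite(bd$u) || bd$u <= 0 || bd$u < cfg$quorum) next
        for (t in seq_len(total)) {
          draws[t, b] <- sqs_draw(bd, cfg, sample(bd$coll_ids))
        }
      }
    } else {
      cand <- binned$candidates
      multi <- lengths(cand) > 1L
      base_bin <- vapply(cand, function(z) z[1L], integer(1L))
      for (t in seq_len(total)) {
        bin_t <- base_bin
        if (any(multi)) {
          bin_t[multi] <- vapply(cand[multi], function(z) z[sample.int(length(z), 1L)],
                                 integer(1L))
        }
        for (b in unique(bin_t)) {
          occs <- binned$table[bin_t == b, , drop = FALSE]
          bd <- sqs_bin_data(occs$taxon, occs$collection_id, occs$publication_id, cfg)
          observed[b] <- max(observed[b], bd$richness)
          u_rec[t, b] <- bd$u
          if (!is.finite(bd$u) || bd$u <= 0 || bd$u < cfg$quorum) next
          draws[t, b] <- sqs_draw(bd, cfg, sample(bd$coll_ids))
        }
      }
    }
    n_def <- colSums(!is.na(draws))
    out <- data.frame(
      bin = scheme$label, midpoint = scheme$midpoint,
      u = colMeans(u_rec, na.rm = TRUE),
      mean = ifelse(n_def > 0, colMeans(draws, na.rm = TRUE), NA_real_),
      sd = apply(draws, 2L, function(z) if (sum(!is.na(z)) > 1L) stats::sd(z, na.rm = TRUE) else NA_real_),
      n_trials = n_def, observed = observed, stringsAsFactors = FALSE
    )
    out$u[is.nan(out$u)] <- NA_real_
    if (cfg$replicates > 1L) {
      rep_id <- rep(seq_len(cfg$replicates), each = cfg$trials)
      rep_means <- apply(draws, 2L, function(z) {
        tapply(z, rep_id, function(w) if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE))
      })
      attr(out, "replicate_means") <- rep_means
    }
    attr(out, "config") <- cfg
    class(out) <- c("sqs_result", "data.frame")
    out
  })
}

#' @export
print.sqs_result <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("SQS estimate (%s dialect, q = %g): %d bins, %d defined\n",
              cfg$dialect, cfg$quorum, nrow(x), sum(!is.na(x$mean))))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}
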