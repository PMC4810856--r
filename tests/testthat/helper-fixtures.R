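# Shared fixtures and independent oracles, built in code at test time.

toy_scheme <- function() {
  bin_scheme(c("b1", "b2", "b3"), older = c(160, 150, 140),
             younger = c(150, 140, 130), name = "toy")
}

# 10-row table: 6 nonmarine (4 Europe, 2 Asia), 4 marine (Europe/Other)
toy_occ_df <- function() {
  data.frame(
    occurrence_id = paste0("o", 1:10),
    genus = c("Alpha", "Alpha", "Beta", "Beta", "Gamma",
              "Delta", "Delta", "Epsilon", "Zeta", "Zeta"),
    species = c("prima", "", "secunda", "secunda", "", "", "tertia", "", "", ""),
    collection_id = c("c1", "c1", "c2", "c3", "c3", "c4", "c5", "c5", "c6", "c6"),
    publication_id = c("p1", "p1", "p1", "p2", "p2", "p2", "p3", "p3", "p3", "p3"),
    age_max = c(158, 156, 155, 148, 147, 146, 145, 138, 136, 134),
    age_min = c(156, 154, 152, 146, 145, 144, 143, 136, 134, 132),
    realm = c("nonmarine", "nonmarine", "marine", "nonmarine", "marine",
              "nonmarine", "marine", "nonmarine", "nonmarine", "marine"),
    continent = c("Europe", "Europe", "Europe", "Asia", "Europe",
                  "Asia", "Other", "Europe", "Europe", "Other"),
    stringsAsFactors = FALSE
  )
}

toy_occurrences <- function() occurrence_table(toy_occ_df())

write_occ_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# single-bin occurrence set for subsampling tests: `spec` is a list of
# collections, each a list(pub = <id>, taxa = <character vector, one entry
# per occurrence>)
make_bin_occs <- function(spec) {
  rows <- do.call(rbind, lapply(seq_along(spec), function(i) {
    data.frame(taxon = spec[[i]]$taxa,
               collection_id = sprintf("c%02d", i),
               publication_id = spec[[i]]$pub,
               stringsAsFactors = FALSE)
  }))
  rows
}

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out <- c(out, list(c(v[i], p)))
  }
  out
}

# Independent subsampling oracle: a direct, stand-alone transcription of the
# drawing rules, structured differently from the package implementation
# (explicit active-publication state machine, no precomputed bin structures).
oracle_sqs <- function(occs, order, quorum, dialect = "throttled", pubs_cap = 3,
                       exclude_singletons = TRUE, include_dominant = TRUE,
                       dominant_share = FALSE, correct_dominant = TRUE) {
  counts <- table(occs$taxon)
  O <- sum(counts)
  s1 <- sum(counts == 1)
  n_dom <- max(counts)
  dom <- names(counts)[which.max(counts)]
  den_u <- if (correct_dominant) O - n_dom else O
  u <- if (den_u <= 0) (if (s1 > 0) 0 else 1) else min(1, max(0, 1 - s1 / den_u))
  if (u <= 0 || u < quorum) return(NA_integer_)
  den_s <- if (dominant_share) O else O - n_dom
  share_of <- function(tx) {
    if (!dominant_share && tx == dom) 0 else as.numeric(counts[tx]) / den_s
  }
  pub_of <- vapply(order, function(cid) {
    occs$publication_id[match(cid, occs$collection_id)][1L]
  }, character(1L))
  names(pub_of) <- order
  target <- quorum / u
  taken <- character(0)
  pub_used <- integer(0)
  seen <- character(0)
  acc <- 0
  tally <- 0L
  active <- NA_character_
  repeat {
    avail <- setdiff(order, taken)
    avail <- avail[vapply(avail, function(cid) {
      p <- pub_of[[cid]]
      (if (p %in% names(pub_used)) pub_used[[p]] else 0L) < pubs_cap
    }, logical(1L))]
    if (!length(avail)) break
    if (dialect == "throttled" && !is.na(active) && any(pub_of[avail] == active)) {
      cid <- avail[pub_of[avail] == active][1L]
    } else {
      cid <- avail[1L]
    }
    taken <- c(taken, cid)
    p <- pub_of[[cid]]
    pub_used[p] <- (if (p %in% names(pub_used)) pub_used[[p]] else 0L) + 1L
    active <- if (dialect == "throttled" && pub_used[[p]] < pubs_cap) p else NA_character_
    for (tx in unique(occs$taxon[occs$collection_id == cid])) {
      if (tx %in% seen) next
      seen <- c(seen, tx)
      acc <- acc + share_of(tx)
      ok <- TRUE
      if (!include_dominant && tx == dom) ok <- FALSE
      if (exclude_singletons && counts[tx] == 1) ok <- FALSE
      if (ok) tally <- tally + 1L
    }
    if (acc >= target - 1e-12) break
  }
  tally
}

# normalised (mean-1) L1 distance between an estimated and a true
# trajectory over jointly defined bins
rel_l1 <- function(est, tru, defined) {
  e <- est[defined] / mean(est[defined])
  t <- tru[defined] / mean(tru[defined])
  mean(abs(e - t))
}
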