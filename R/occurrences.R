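#' Construct an occurrence table
#'
#' The central flat container for body-fossil occurrence data: one row per
#' occurrence, with taxonomy, collection and publication identifiers, an age
#' range in Ma, and realm/continent attributes. Occurrences must be
#' identifiable to genus; rows with an empty genus are rejected by
#' [read_occurrences()] before this constructor is reached.
#'
#' @param df A data.frame with columns `occurrence_id`, `taxon`, `genus`,
#'   `species`, `collection_id`, `publication_id`, `age_max`, `age_min`,
#'   `realm`, `continent`. `species` may be empty (specifically indeterminate
#'   occurrences); `taxon` defaults to the genus, or "genus species" when a
#'   species epithet is present.
#' @return An `occurrence_table` (a classed data.frame).
#' @export
occurrence_table <- function(df) {
  need <- c("occurrence_id", "genus", "collection_id", "publication_id",
            "age_max", "age_min", "realm", "continent")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("occurrence table lacks column(s): ", paste(miss, collapse = ", "))
  df$genus <- as.character(df$genus)
  if (is.null(df$species)) df$species <- ""
  df$species <- ifelse(is.na(df$species), "", as.character(df$species))
  if (is.null(df$taxon)) {
    df$taxon <- ifelse(nzchar(df$species), paste(df$genus, df$species), df$genus)
  }
  df$age_max <- as.numeric(df$age_max)
  df$age_min <- as.numeric(df$age_min)
  bad_age <- which(is.na(df$age_max) | is.na(df$age_min))
  if (length(bad_age)) {
    stop("unparseable age for occurrence id(s): ",
         paste(utils::head(df$occurrence_id[bad_age], 5L), collapse = ", "))
  }
  inv <- which(df$age_max < df$age_min | df$age_min <= 0)
  if (length(inv)) {
    stop("invalid age range (need age_max >= age_min > 0) for occurrence id(s): ",
         paste(utils::head(df$occurrence_id[inv], 5L), collapse = ", "))
  }
  blank <- which(!nzchar(df$genus) | is.na(df$genus))
  if (length(blank)) stop("empty genus for occurrence id(s): ",
                          paste(utils::head(df$occurrence_id[blank], 5L), collapse = ", "))
  bad_realm <- setdiff(unique(df$realm), c("marine", "nonmarine"))
  if (length(bad_realm)) stop("unknown realm value(s): ", paste(bad_realm, collapse = ", "))
  cols <- c("occurrence_id", "taxon", "genus", "species", "collection_id",
            "publication_id", "age_max", "age_min", "realm", "continent")
  out <- df[, cols]
  rownames(out) <- NULL
  class(out) <- c("occurrence_table", "data.frame")
  out
}

#' @export
print.occurrence_table <- function(x, ...) {
  cat(sprintf("Occurrence table: %d occurrences, %d genera, %d collections\n",
              nrow(x), length(unique(x$genus)), length(unique(x$collection_id))))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Read occurrences from a PaleoDB-style CSV export
#'
#' Column names in the file are mapped onto the canonical occurrence fields
#' via `column_map`. Rows that cannot be assigned to a genus (empty or
#' missing genus) are dropped with a reported count, following the rule that
#' only occurrences identifiable to genus enter the analysis. Rows with an
#' unparseable or inverted age range raise an error naming the offending
#' occurrence id.
#'
#' @param path CSV file path.
#' @param column_map Named character vector or list mapping canonical field
#'   names (`occurrence_id`, `genus`, `species`, `collection_id`,
#'   `publication_id`, `age_max`, `age_min`, `realm`, `continent`) to column
#'   names in the file. Fields absent from the map use their canonical name.
#' @return An [occurrence_table] with attribute `n_dropped_no_genus`.
#' @export
read_occurrences <- function(path, column_map = list()) {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  fields <- c("occurrence_id", "genus", "species", "collection_id",
              "publication_id", "age_max", "age_min", "realm", "continent")
  cmap <- as.list(column_map)
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in fields) {
    src <- cmap[[f]] %||% f
    if (!src %in% names(raw)) {
      if (f == "species") { df[[f]] <- ""; next }
      stop("mapped column '", src, "' (field '", f, "') not present in ", path)
    }
    df[[f]] <- raw[[src]]
  }
  no_genus <- !nzchar(trimws(df$genus)) | is.na(df$genus)
  n_dropped <- sum(no_genus)
  if (n_dropped) {
    message(n_dropped, " occurrence(s) dropped: not assignable to genus")
    df <- df[!no_genus, , drop = FALSE]
  }
  num <- suppressWarnings(list(age_max = as.numeric(df$age_max),
                               age_min = as.numeric(df$age_min)))
  bad <- which(is.na(num$age_max) | is.na(num$age_min))
  if (length(bad)) {
    stop("unparseable age for occurrence id(s): ",
         paste(utils::head(df$occurrence_id[bad], 5L), collapse = ", "))
  }
  df$age_max <- num$age_max
  df$age_min <- num$age_min
  out <- occurrence_table(df)
  attr(out, "n_dropped_no_genus") <- n_dropped
  out
}

#' Remove occurrences matching exclusion rules
#'
#' Each rule names a genus and, optionally, an age window (Ma) within which
#' occurrences of that genus are considered spurious and removed — the
#' mechanism used to drop, e.g., Mesozoic records of extant genera or
#' post-boundary records of clades known to have gone extinct.
#'
#' @param table An [occurrence_table].
#' @param rules A list of rules; each rule is a list with `genus` (or
#'   `genera`, a character vector) and optional `age_max`, `age_min` giving
#'   the window (occurrence removed when its range overlaps the window).
#' @return The filtered [occurrence_table], with attribute `removals`: a
#'   per-rule count of removed rows.
#' @export
apply_filters <- function(table, rules = list()) {
  stopifnot(inherits(table, "occurrence_table"))
  removed <- integer(length(rules))
  keep <- rep(TRUE, nrow(table))
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    extra <- setdiff(names(r), c("genus", "genera", "age_max", "age_min", "label"))
    if (length(extra)) stop("filter rule ", i, " references unknown field(s): ",
                            paste(extra, collapse = ", "))
    gen <- r$genera %||% r$genus
    if (is.null(gen)) stop("filter rule ", i, " lacks a genus")
    hit <- table$genus %in% gen
    if (!is.null(r$age_max)) hit <- hit & table$age_min <= r$age_max
    if (!is.null(r$age_min)) hit <- hit & table$age_max >= r$age_min
    removed[i] <- sum(hit & keep)
    keep <- keep & !hit
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(table)
  attr(out, "removals") <- removed
  out
}

#' Subset occurrences by realm or continent
#'
#' The realm split is a partition: `subset_occurrences(x, realm = "marine")`
#' and `realm = "nonmarine"` together recover every row exactly once.
#'
#' @param table An [occurrence_table].
#' @param realm Optional realm value ("marine" or "nonmarine").
#' @param continent Optional continent value.
#' @return The filtered [occurrence_table].
#' @export
subset_occurrences <- function(table, realm = NULL, continent = NULL) {
  stopifnot(inherits(table, "occurrence_table"))
  keep <- rep(TRUE, nrow(table))
  if (!is.null(realm)) {
    if (!realm %in% c("marine", "nonmarine")) stop("unknown realm: ", realm)
    keep <- keep & table$realm == realm
  }
  if (!is.null(continent)) keep <- keep & table$continent == continent
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(table)
  out
}

#' Assign occurrences to time bins
#'
#' Under the `constrained` policy an occurrence is retained only if its full
#' age range `[age_min, age_max]` lies within a single bin (half-open bins,
#' older bound inclusive); occurrences whose range overlaps more than one bin
#' are dropped with a reported count. Under `unconstrained`, every occurrence
#' inside the scheme span is retained with the full set of candidate bins its
#' range overlaps; stochastic consumers (e.g. subsampling trials) resolve the
#' ambiguity per trial. Occurrences wholly outside the scheme span are
#' excluded under both policies.
#'
#' @param table An [occurrence_table].
#' @param scheme A [bin_scheme].
#' @param policy `"constrained"` or `"unconstrained"`.
#' @return A `binned_occurrences` object: list with `table` (retained rows;
#'   under constrained with integer column `bin` and label column
#'   `bin_label`), `candidates` (unconstrained: list of candidate bin index
#'   vectors), `scheme`, `policy`, and drop counts `n_multibin_dropped`,
#'   `n_out_of_span`.
#' @export
assign_to_bins <- function(table, scheme, policy = c("constrained", "unconstrained")) {
  stopifnot(inherits(table, "occurrence_table"), inherits(scheme, "bin_scheme"))
  policy <- match.arg(policy)
  cand <- lapply(seq_len(nrow(table)), function(i) {
    candidate_bins(scheme, table$age_max[i], table$age_min[i])
  })
  n_cand <- lengths(cand)
  out_of_span <- n_cand == 0L
  if (policy == "constrained") {
    single <- n_cand == 1L
    # containment, not mere overlap: the range must sit inside its one bin
    contained <- single
    for (i in which(single)) {
      b <- cand[[i]]
      lower_ok <- if (b == nrow(scheme)) table$age_min[i] >= scheme$younger[b]
                  else table$age_min[i] > scheme$younger[b]
      contained[i] <- table$age_max[i] <= scheme$older[b] && lower_ok
    }
    keep <- contained
    tab <- table[keep, , drop = FALSE]
    bins <- vapply(cand[keep], identity, integer(1L))
    tab$bin <- bins
    tab$bin_label <- scheme$label[bins]
    rownames(tab) <- NULL
    class(tab) <- class(table)
    res <- list(table = tab, candidates = NULL, scheme = scheme,
                policy = policy,
                n_multibin_dropped = sum(!keep & !out_of_span),
                n_out_of_span = sum(out_of_span))
  } else {
    keep <- !out_of_span
    tab <- table[keep, , drop = FALSE]
    rownames(tab) <- NULL
    class(tab) <- class(table)
    res <- list(table = tab, candidates = cand[keep], scheme = scheme,
                policy = policy, n_multibin_dropped = 0L,
                n_out_of_span = sum(out_of_span))
  }
  class(res) <- "binned_occurrences"
  res
}

#' @export
print.binned_occurrences <- function(x, ...) {
  cat(sprintf("Binned occurrences (%s policy): %d retained over %d bins; %d multi-bin dropped, %d out of span\n",
              x$policy, nrow(x$table), nrow(x$scheme),
              x$n_multibin_dropped, x$n_out_of_span))
  invisible(x)
}

# Taxon identity at a rank; species-rank analyses use only rows with an
# epithet.
rank_identity <- function(table, rank = c("genus", "species")) {
  rank <- match.arg(rank)
  if (rank == "genus") {
    list(keep = rep(TRUE, nrow(table)), id = table$genus)
  } else {
    keep <- nzchar(table$species)
    list(keep = keep, id = paste(table$genus, table$species)[keep])
  }
}

diversity_series <- function(scheme, values, sd = NULL, label = "diversity") {
  out <- data.frame(bin = scheme$label, midpoint = scheme$midpoint,
                    value = values,
                    sd = if (is.null(sd)) NA_real_ else sd,
                    stringsAsFactors = FALSE)
  attr(out, "label") <- label
  attr(out, "scheme_name") <- attr(scheme, "name")
  class(out) <- c("diversity_series", "data.frame")
  out
}

#' Raw taxonomic diversity estimate (TDE)
#'
#' Uncorrected per-bin count of distinct taxa at the requested rank.
#' Requires constrained binning: raw in-bin counts need each occurrence in
#' exactly one bin. Duplicate occurrences of the same taxon collapse to one
#' in the count.
#'
#' @param binned A `binned_occurrences` object (constrained policy).
#' @param rank `"genus"` or `"species"`.
#' @return A `diversity_series` data.frame (`bin`, `midpoint`, `value`, `sd`).
#' @export
tde <- function(binned, rank = c("genus", "species")) {
  stopifnot(inherits(binned, "binned_occurrences"))
  if (binned$policy != "constrained") {
    stop("tde requires constrained binning; re-bin with policy = 'constrained' ",
         "or resolve multi-bin occurrences before counting")
  }
  rank <- match.arg(rank)
  ri <- rank_identity(binned$table, rank)
  bins <- binned$table$bin[ri$keep]
  vals <- integer(nrow(binned$scheme))
  if (length(bins)) {
    agg <- tapply(ri$id, bins, function(z) length(unique(z)))
    vals[as.integer(names(agg))] <- as.integer(agg)
  }
  diversity_series(binned$scheme, vals, label = paste0("TDE_", rank))
}

#' Taxon stratigraphic ranges
#'
#' For each taxon at the given rank: first appearance datum (FAD) = the
#' oldest `age_max` over its occurrences, last appearance datum (LAD) = the
#' youngest `age_min`, plus the bins of the occurrences providing them.
#'
#' @param binned A `binned_occurrences` object (constrained policy).
#' @param rank `"genus"` or `"species"`.
#' @return A data.frame with columns `taxon`, `fad`, `lad`, `fad_bin`,
#'   `lad_bin` (bin labels).
#' @export
taxon_ranges <- function(binned, rank = c("genus", "species")) {
  stopifnot(inherits(binned, "binned_occurrences"))
  if (binned$policy != "constrained") stop("taxon_ranges requires constrained binning")
  rank <- match.arg(rank)
  ri <- rank_identity(binned$table, rank)
  tab <- binned$table[ri$keep, , drop = FALSE]
  if (!nrow(tab)) {
    return(data.frame(taxon = character(0), fad = numeric(0), lad = numeric(0),
                      fad_bin = character(0), lad_bin = character(0),
                      fad_bin_idx = integer(0), lad_bin_idx = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab$.id <- ri$id
  sp <- split(tab, tab$.id)
  out <- do.call(rbind, lapply(sp, function(d) {
    i_fad <- which.max(d$age_max)
    i_lad <- which.min(d$age_min)
    data.frame(taxon = d$.id[1L], fad = d$age_max[i_fad], lad = d$age_min[i_lad],
               fad_bin = d$bin_label[i_fad], lad_bin = d$bin_label[i_lad],
               fad_bin_idx = d$bin[i_fad], lad_bin_idx = d$bin[i_lad],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$taxon), , drop = FALSE]
}
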