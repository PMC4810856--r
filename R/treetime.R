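#' Read / write Newick trees
#'
#' Thin wrappers around ape's Newick parser that fail loudly on malformed
#' input. Round-tripping preserves topology and tip labels.
#'
#' @param path File path.
#' @return `read_newick`: an `ape::phylo`. `write_newick`: the path,
#'   invisibly.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("Newick parse error in ", path)
  if (any(duplicated(tr$tip.label))) stop("duplicate tip labels in ", path)
  tr
}

#' @param tree An `ape::phylo` or a `dated_tree` (its topology is written).
#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "dated_tree")) tree <- tree$tree
  ape::write.tree(tree, file = path)
  invisible(path)
}

# children adjacency list and parent vector from a phylo edge matrix
tree_index <- function(tree) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  children <- vector("list", n_all)
  parent <- integer(n_all)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; c <- tree$edge[i, 2L]
    children[[p]] <- c(children[[p]], c)
    parent[c] <- p
  }
  root <- ape::Ntip(tree) + 1L
  list(children = children, parent = parent, root = root, ntip = ape::Ntip(tree))
}

# tip labels under each node
tips_under <- function(tree, idx = tree_index(tree)) {
  n_all <- idx$ntip + tree$Nnode
  out <- vector("list", n_all)
  po <- rev(preorder_nodes(idx))
  for (v in po) {
    out[[v]] <- if (v <= idx$ntip) tree$tip.label[v]
                else unlist(lapply(idx$children[[v]], function(w) out[[w]]))
  }
  out
}

preorder_nodes <- function(idx) {
  out <- integer(0)
  stack <- idx$root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, rev(idx$children[[v]]))
  }
  out
}

# nested-list representation (tips as label strings), used by the ordered
# polytomy resolver
phylo_to_nested <- function(tree) {
  idx <- tree_index(tree)
  rec <- function(v) {
    if (v <= idx$ntip) return(tree$tip.label[v])
    lapply(idx$children[[v]], rec)
  }
  rec(idx$root)
}

nested_to_newick <- function(x) {
  rec <- function(z) {
    if (is.character(z)) return(z)
    paste0("(", paste(vapply(z, rec, character(1L)), collapse = ","), ")")
  }
  paste0(rec(x), ";")
}

nested_fad <- function(z, fads) {
  if (is.character(z)) return(fads[[z]])
  max(vapply(z, nested_fad, numeric(1L), fads = fads))
}

#' Resolve polytomies
#'
#' Three policies: `"equal"` leaves the topology untouched (zero-length
#' branches arising at polytomies are handled later by the equal
#' time-scaling redistribution); `"random"` resolves each polytomy uniformly
#' at random; `"ordered"` resolves each polytomy so that lineages branch in
#' order of first stratigraphic appearance — the oldest-FAD child diverges
#' first, producing a caterpillar — with equal first appearances broken at
#' random.
#'
#' @param tree An `ape::phylo`.
#' @param method `"equal"`, `"random"` or `"ordered"`.
#' @param fads Named numeric vector of tip first-appearance ages (Ma);
#'   required for `"ordered"`.
#' @param seed Optional integer seed for the stochastic policies.
#' @return A `phylo`; fully binary for `"random"` and `"ordered"`.
#' @export
resolve_polytomies <- function(tree, method = c("equal", "random", "ordered"),
                               fads = NULL, seed = NULL) {
  method <- match.arg(method)
  if (method == "equal") return(tree)
  with_seed(seed, {
    if (method == "random") {
      out <- ape::multi2di(tree, random = TRUE)
      out$edge.length <- NULL
      return(out)
    }
    miss <- setdiff(tree$tip.label, names(fads))
    if (length(miss)) stop("ordered resolution needs a FAD for tip(s): ",
                           paste(miss, collapse = ", "))
    rec <- function(z) {
      if (is.character(z)) return(z)
      z <- lapply(z, rec)
      if (length(z) > 2L) {
        f <- vapply(z, nested_fad, numeric(1L), fads = fads)
        # oldest first appearance branches first; ties broken randomly
        ord <- order(-f, stats::runif(length(f)))
        z <- z[ord]
        cat_tree <- z[[length(z)]]
        for (j in rev(seq_len(length(z) - 1L))) cat_tree <- list(z[[j]], cat_tree)
        return(cat_tree)
      }
      z
    }
    nested <- rec(phylo_to_nested(tree))
    ape::read.tree(text = nested_to_newick(nested))
  })
}

#' Time-scale a tree on stratigraphic first appearances
#'
#' Basic a-posteriori dating sets each internal node's age to the oldest
#' first-appearance datum among its descendant tips and each tip's age to
#' its own FAD, which typically creates zero-length branches wherever a node
#' subtends the taxon that dates it. A stem of `root_extension` Myr is hung
#' above the root. Under `method = "equal"` the zero-length branches are then
#' removed by redistribution: each run of zero-length branches shares,
#' equally, the duration of the first ancestral branch of positive length
#' (the stem supplies the slack at the root). Where no ancestral slack exists
#' the branch stays at zero length and is flagged. `"random"` and
#' `"ordered"` first resolve polytomies (see [resolve_polytomies()]) and then
#' apply basic dating, matching the usual a-posteriori time-scaling of
#' supertrees.
#'
#' @param tree An `ape::phylo`.
#' @param fads Named numeric vector of tip first appearances (Ma); every tip
#'   must be present.
#' @param lads Optional named numeric vector of tip last appearances (Ma);
#'   tips lacking one use `lad = fad` (point occurrences).
#' @param method Polytomy/dating policy: `"equal"`, `"random"`, `"ordered"`.
#' @param root_extension Stem length added above the oldest FAD, in Myr
#'   (default 5; reported in the object metadata).
#' @param seed Optional seed for the stochastic methods.
#' @return A `dated_tree`: list with `tree` (edge lengths in Myr,
#'   `root.edge` = stem), `ages` (node ages, Ma), `fad`, `lad`, `stem_top`,
#'   `method`, `root_extension`, and `n_zero_flagged` (zero-length branches
#'   that could not be extended).
#' @export
time_scale <- function(tree, fads, lads = NULL,
                       method = c("equal", "random", "ordered"),
                       root_extension = 5, seed = NULL) {
  method <- match.arg(method)
  miss <- setdiff(tree$tip.label, names(fads))
  if (length(miss)) stop("no FAD for tip(s): ", paste(miss, collapse = ", "))
  tree <- resolve_polytomies(tree, method, fads = fads, seed = seed)
  idx <- tree_index(tree)
  n_all <- idx$ntip + tree$Nnode
  ages <- numeric(n_all)
  for (v in rev(preorder_nodes(idx))) {
    ages[v] <- if (v <= idx$ntip) fads[[tree$tip.label[v]]]
               else max(ages[idx$children[[v]]])
  }
  stem_top <- ages[idx$root] + root_extension
  n_flagged <- 0L
  tol <- 1e-8
  if (method == "equal") {
    # Zero-length runs are redistributed shallowest-first (breadth-first),
    # with a canonical within-level order (alphabetically by the child
    # clade's first tip label), so the result does not depend on tip input
    # order: a run near the root is resolved before deeper runs in any
    # subtree draw on the ancestral slack it creates.
    pre <- preorder_nodes(idx)
    depth <- integer(idx$ntip + tree$Nnode)
    for (v in pre) if (v != idx$root) depth[v] <- depth[idx$parent[v]] + 1L
    tu <- tips_under(tree, idx)
    min_lab <- vapply(tu, function(z) min(z), character(1L))
    cand <- pre[pre != idx$root]
    edge_order <- cand[order(depth[cand], min_lab[cand])]
    for (c_node in edge_order) {
      p <- idx$parent[c_node]
      if (ages[p] - ages[c_node] > tol) next
      T_age <- if (p == idx$root) stem_top else ages[idx$parent[p]]
      B <- ages[c_node]
      if (T_age - B <= tol) { n_flagged <- n_flagged + 1L; next }
      # grow the run of zero-length branches below this one
      chain_tops <- p
      cur <- c_node
      while (cur > idx$ntip) {
        zc <- idx$children[[cur]][ages[cur] - ages[idx$children[[cur]]] <= tol]
        if (length(zc) != 1L) break
        chain_tops <- c(chain_tops, cur)
        cur <- zc
      }
      B <- ages[cur]
      k1 <- length(chain_tops) + 1L # zero branches + the ancestral donor
      ages[chain_tops] <- T_age - seq_along(chain_tops) * (T_age - B) / k1
    }
  }
  tree$edge.length <- ages[tree$edge[, 1L]] - ages[tree$edge[, 2L]]
  tree$root.edge <- stem_top - ages[idx$root]
  lad <- stats::setNames(fads[tree$tip.label], tree$tip.label)
  if (!is.null(lads)) {
    hit <- intersect(names(lads), tree$tip.label)
    lad[hit] <- lads[hit]
  }
  structure(list(tree = tree, ages = ages,
                 fad = stats::setNames(fads[tree$tip.label], tree$tip.label),
                 lad = lad, stem_top = stem_top, method = method,
                 root_extension = root_extension, n_zero_flagged = n_flagged),
            class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf("Dated tree (%s method): %d tips, root at %.2f Ma (stem to %.2f Ma)\n",
              x$method, ape::Ntip(x$tree), x$ages[ape::Ntip(x$tree) + 1L], x$stem_top))
  invisible(x)
}

#' Extract a dated subtree
#'
#' Restricts a dated tree to a subset of tips (e.g. the marine or the
#' non-marine taxa), excising removed tips and the internal nodes left with
#' a single descendant. Ages of retained nodes are unchanged: each surviving
#' internal node keeps the age it had in the full tree.
#'
#' @param dtree A `dated_tree`.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return A `dated_tree` on the retained tips.
#' @export
drop_tips <- function(dtree, keep) {
  stopifnot(inherits(dtree, "dated_tree"))
  keep <- intersect(dtree$tree$tip.label, keep)
  if (length(keep) < 2L) stop("need at least 2 tips to retain")
  old <- dtree$tree
  new <- ape::keep.tip(old, keep)
  idx <- tree_index(new)
  n_all <- idx$ntip + new$Nnode
  ages <- numeric(n_all)
  ages[seq_len(idx$ntip)] <- dtree$fad[new$tip.label]
  tu <- tips_under(new, idx)
  for (v in (idx$ntip + 1L):n_all) {
    mrca <- if (length(tu[[v]]) == ape::Ntip(old)) ape::Ntip(old) + 1L
            else ape::getMRCA(old, tu[[v]])
    ages[v] <- dtree$ages[mrca]
  }
  new$edge.length <- ages[new$edge[, 1L]] - ages[new$edge[, 2L]]
  new$root.edge <- dtree$stem_top - ages[idx$root]
  structure(list(tree = new, ages = ages,
                 fad = dtree$fad[new$tip.label], lad = dtree$lad[new$tip.label],
                 stem_top = dtree$stem_top, method = dtree$method,
                 root_extension = dtree$root_extension,
                 n_zero_flagged = dtree$n_zero_flagged),
            class = "dated_tree")
}

# (top, bottom) age span of every lineage segment: each edge, tips extended
# to their LAD, plus the root stem
lineage_spans <- function(dtree) {
  tree <- dtree$tree
  ntip <- ape::Ntip(tree)
  top <- dtree$ages[tree$edge[, 1L]]
  child <- tree$edge[, 2L]
  bottom <- dtree$ages[child]
  is_tip <- child <= ntip
  bottom[is_tip] <- pmin(bottom[is_tip], dtree$lad[tree$tip.label[child[is_tip]]])
  cbind(top = c(top, dtree$stem_top),
        bottom = c(bottom, dtree$ages[ntip + 1L]))
}

#' Phylogenetic diversity estimate (PDE)
#'
#' Per-bin count of lineages implied by a time-scaled tree: every edge,
#' extended at the tips to each taxon's last appearance, contributes to each
#' bin its time span intersects (half-open bins, older bound inclusive, as
#' elsewhere). Ghost lineages — branch segments older than their taxon's
#' first appearance — are counted automatically, so PDE is never below the
#' in-bin sampled taxon count. A lineage that originates and ends inside one
#' bin counts once in that bin.
#'
#' @param dtree A `dated_tree`.
#' @param scheme A [bin_scheme].
#' @return A `diversity_series` data.frame.
#' @export
pde <- function(dtree, scheme) {
  stopifnot(inherits(dtree, "dated_tree"), inherits(scheme, "bin_scheme"))
  sp <- lineage_spans(dtree)
  nb <- nrow(scheme)
  vals <- vapply(seq_len(nb), function(b) {
    top_ok <- if (b == nb) sp[, "top"] >= scheme$younger[b] else sp[, "top"] > scheme$younger[b]
    sum(top_ok & sp[, "bottom"] <= scheme$older[b])
  }, numeric(1L))
  diversity_series(scheme, vals, label = paste0("PDE_", dtree$method))
}

#' Mean-of-methods PDE
#'
#' Runs the equal, random and ordered dating policies on one tree and
#' reports each per-bin series together with their mean — the headline PDE.
#' The stochastic policies (random, ordered with ties) are averaged over
#' `n_resolutions` seeded resolutions each.
#'
#' @param tree An `ape::phylo` (may contain polytomies).
#' @param fads,lads Named tip first/last appearance ages (Ma).
#' @param scheme A [bin_scheme].
#' @param methods Dating policies to run.
#' @param n_resolutions Seeded resolutions averaged per stochastic policy
#'   (default 100).
#' @param root_extension Stem length in Myr.
#' @param seed Master seed; per-resolution seeds are derived from it.
#' @return List with `methods` (named list of `diversity_series`) and `mean`
#'   (a `diversity_series`; `sd` column holds the across-method sd).
#' @export
pde_estimate <- function(tree, fads, lads = NULL, scheme,
                         methods = c("equal", "random", "ordered"),
                         n_resolutions = 100L, root_extension = 5, seed = NULL) {
  series <- list()
  for (m in methods) {
    if (m == "equal") {
      dt <- time_scale(tree, fads, lads, method = "equal",
                       root_extension = root_extension)
      series[[m]] <- pde(dt, scheme)
    } else {
      reps <- vapply(seq_len(n_resolutions), function(i) {
        dt <- time_scale(tree, fads, lads, method = m,
                         root_extension = root_extension,
                         seed = stage_seed(seed %||% 0L, paste0("pde_", m, "_", i)))
        pde(dt, scheme)$value
      }, numeric(nrow(scheme)))
      s <- diversity_series(scheme, rowMeans(reps),
                            sd = apply(reps, 1L, stats::sd),
                            label = paste0("PDE_", m))
      series[[m]] <- s
    }
  }
  mat <- vapply(series, function(s) s$value, numeric(nrow(scheme)))
  mean_series <- diversity_series(scheme, rowMeans(mat),
                                  sd = apply(mat, 1L, stats::sd),
                                  label = "PDE_mean")
  list(methods = series, mean = mean_series)
}

#' Collapse a species-level dated input to genus level
#'
#' Keeps one tip per genus — the earliest-appearing species — and, by
#' default, pools the genus's stratigraphic range onto it (FAD = oldest
#' species FAD, LAD = youngest species LAD). With
#' `earliest_species_only = TRUE` the representative keeps its own dates.
#'
#' @param tree An `ape::phylo` with species tips.
#' @param fads,lads Named tip ages (Ma).
#' @param genus_of Function mapping a tip label to its genus (default: the
#'   first whitespace- or underscore-delimited word).
#' @param earliest_species_only Keep the representative's own range instead
#'   of the pooled genus range.
#' @return List with `tree`, `fads`, `lads` at genus level (tips relabelled
#'   to genera).
#' @export
collapse_to_genus <- function(tree, fads, lads = NULL,
                              genus_of = function(x) sub("[ _].*$", "", x),
                              earliest_species_only = FALSE) {
  if (is.null(lads)) lads <- fads[tree$tip.label]
  gen <- vapply(tree$tip.label, genus_of, character(1L))
  keep <- character(0)
  new_fad <- new_lad <- numeric(0)
  for (g in unique(gen)) {
    tips <- tree$tip.label[gen == g]
    rep_tip <- tips[which.max(fads[tips])]
    keep <- c(keep, rep_tip)
    if (earliest_species_only) {
      new_fad[g] <- fads[[rep_tip]]
      new_lad[g] <- lads[[rep_tip]]
    } else {
      new_fad[g] <- max(fads[tips])
      new_lad[g] <- min(lads[tips])
    }
  }
  out <- if (length(keep) < length(tree$tip.label)) ape::keep.tip(tree, keep) else tree
  out$tip.label <- vapply(out$tip.label, genus_of, character(1L))
  list(tree = out, fads = new_fad[out$tip.label], lads = new_lad[out$tip.label])
}
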