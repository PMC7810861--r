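ARROW_ACT <- "→"   # right arrow
ARROW_INH <- "⊣"   # right tack

# display names used in variant labels (the REST complex node is written
# "REST" in the perturbation tables)
label_node <- function(node) ifelse(node == "RESTc", "REST", node)
unlabel_node <- function(name) ifelse(name == "REST", "RESTc", name)

#' Enumerate all single-edge additions to a base topology
#'
#' All hypothetical single interactions among the four active nodes (PTB,
#' nPTB, RESTc, miRs): every ordered pair with either sign, excluding
#' self-interactions and pairs already carrying an edge in either sign.
#' For the literature network this yields exactly 12 variants.
#'
#' @param base a `grn_topology`.
#' @param among nodes considered for additions.
#' @return named list of `grn_topology` objects; names are edge labels
#'   like `"nPTB → PTB"`.
#' @export
enumerate_single_additions <- function(base,
                                       among = c("PTB", "nPTB", "RESTc",
                                                 "miRs")) {
  stopifnot(inherits(base, "grn_topology"), all(among %in% base$nodes))
  out <- list()
  for (src in among) for (tgt in among) {
    if (src == tgt) next
    if (any(base$edges$source == src & base$edges$target == tgt)) next
    for (sign in c(ACTIVATION, INHIBITION)) {
      topo <- add_edge(base, src, tgt, sign)
      arr <- if (sign == ACTIVATION) ARROW_ACT else ARROW_INH
      out[[paste(label_node(src), arr, label_node(tgt))]] <- topo
    }
  }
  out
}

#' Construct named two-edge variants
#'
#' Adds pairs of interactions to a base topology, named by the field's
#' labelling convention: edges sharing a source are written
#' `"A → B + C"`, chained edges `"A → B → C"` (mixed signs
#' keep their own arrow, e.g. `"REST ⊣ nPTB → PTB"`).
#'
#' @param base a `grn_topology`.
#' @param pairs list; each element is a list/data.frame of two
#'   `(source, target, sign)` triples.
#' @return named list of `grn_topology`.
#' @export
paired_addition_variants <- function(base, pairs) {
  out <- list()
  for (p in pairs) {
    p <- as.data.frame(p, stringsAsFactors = FALSE)
    if (nrow(p) != 2) stop("each pair must contain exactly two edges")
    if (anyDuplicated(paste(p$source, p$target)))
      stop("duplicate edge within a pair")
    topo <- base
    for (i in 1:2) topo <- add_edge(topo, p$source[i], p$target[i],
                                    p$sign[i])
    out[[variant_label(p)]] <- topo
  }
  out
}

#' Label for a set of added edges
#'
#' Round-trips with [parse_variant_label()].
#' @param edges data.frame of added edges (`source`, `target`, `sign`).
#' @return character label.
#' @export
variant_label <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  arr <- ifelse(edges$sign == ACTIVATION, ARROW_ACT, ARROW_INH)
  if (nrow(edges) == 1)
    return(paste(label_node(edges$source), arr,
                 label_node(edges$target)))
  if (nrow(edges) == 2) {
    if (edges$source[1] == edges$source[2] &&
        edges$sign[1] == edges$sign[2])
      return(paste(label_node(edges$source[1]), arr[1],
                   label_node(edges$target[1]), "+",
                   label_node(edges$target[2])))
    # chain: target of one edge is the source of the other
    ord <- if (edges$target[1] == edges$source[2]) 1:2 else
           if (edges$target[2] == edges$source[1]) 2:1 else NULL
    if (!is.null(ord)) {
      e <- edges[ord, ]
      a <- ifelse(e$sign == ACTIVATION, ARROW_ACT, ARROW_INH)
      return(paste(label_node(e$source[1]), a[1], label_node(e$target[1]),
                   a[2], label_node(e$target[2])))
    }
  }
  paste(paste(label_node(edges$source), arr, label_node(edges$target)),
        collapse = " & ")
}

#' Parse a variant label back into its added edges
#' @param label character label as produced by [variant_label()].
#' @return data.frame of edges (`source`, `target`, `sign`).
#' @export
parse_variant_label <- function(label) {
  tok <- strsplit(trimws(label), "\\s+")[[1]]
  sign_of <- function(a) if (a == ARROW_ACT) ACTIVATION else
    if (a == ARROW_INH) INHIBITION else stop("bad arrow token: ", a)
  if (length(tok) == 3) {
    return(data.frame(source = unlabel_node(tok[1]),
                      target = unlabel_node(tok[3]),
                      sign = sign_of(tok[2]), stringsAsFactors = FALSE))
  }
  if (length(tok) == 5 && tok[4] == "+") {
    s <- unlabel_node(tok[1]); sg <- sign_of(tok[2])
    return(data.frame(source = c(s, s),
                      target = unlabel_node(c(tok[3], tok[5])),
                      sign = c(sg, sg), stringsAsFactors = FALSE))
  }
  if (length(tok) == 5) {
    return(data.frame(
      source = unlabel_node(c(tok[1], tok[3])),
      target = unlabel_node(c(tok[3], tok[5])),
      sign = c(sign_of(tok[2]), sign_of(tok[4])),
      stringsAsFactors = FALSE))
  }
  stop("cannot parse variant label: ", label)
}

#' The named two-interaction variants of the comparison table
#'
#' `nPTB → REST + PTB` (nPTB activates both REST and PTB),
#' `nPTB → REST → PTB` (chain) and
#' `REST ⊣ nPTB → PTB`.
#' @param base base topology (default: literature network).
#' @return named list of `grn_topology`.
#' @export
table2_variants <- function(base = literature_topology()) {
  pairs <- list(
    data.frame(source = c("nPTB", "nPTB"), target = c("RESTc", "PTB"),
               sign = c(ACTIVATION, ACTIVATION), stringsAsFactors = FALSE),
    data.frame(source = c("nPTB", "RESTc"), target = c("RESTc", "PTB"),
               sign = c(ACTIVATION, ACTIVATION), stringsAsFactors = FALSE),
    data.frame(source = c("RESTc", "nPTB"), target = c("nPTB", "PTB"),
               sign = c(INHIBITION, ACTIVATION), stringsAsFactors = FALSE))
  paired_addition_variants(base, pairs)
}

#' Optional edge blocks added to every compared variant
#'
#' `with_mirs_to_ascl1` adds miRs → Ascl1 (an activation letting
#' Ascl1 switch on at the right time without constraining RESTc);
#' `with_ptb_nptb_inhibitions` adds the experimentally observed PTB and
#' nPTB self-inhibitions plus nPTB ⊣ PTB (self-edges are admitted
#' only through this flag).
#'
#' @param base a `grn_topology`.
#' @param added_edges data.frame of extra edges (may be NULL).
#' @param with_mirs_to_ascl1,with_ptb_nptb_inhibitions logical flags.
#' @return a `grn_topology` with all requested edges.
#' @export
variant_family <- function(base, added_edges = NULL,
                           with_mirs_to_ascl1 = FALSE,
                           with_ptb_nptb_inhibitions = FALSE) {
  topo <- base
  if (!is.null(added_edges)) {
    added_edges <- as.data.frame(added_edges, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(added_edges)))
      topo <- add_edge(topo, added_edges$source[i], added_edges$target[i],
                       added_edges$sign[i])
  }
  if (with_mirs_to_ascl1)
    topo <- add_edge(topo, "miRs", "Ascl1", ACTIVATION)
  if (with_ptb_nptb_inhibitions) {
    topo <- add_edge(topo, "PTB", "PTB", INHIBITION, allow_self = TRUE)
    topo <- add_edge(topo, "nPTB", "nPTB", INHIBITION, allow_self = TRUE)
    topo <- add_edge(topo, "nPTB", "PTB", INHIBITION)
  }
  topo
}

#' Comparative fitting of topology variants
#'
#' Fits each variant to the same dataset with `n_restarts` independent
#' GA runs (distinct seeds) and ranks variants by their best fitness, the
#' raw model-selection logic of the topology comparison (no complexity
#' penalty).
#'
#' @param variants named list of `grn_topology`.
#' @param dataset a `grn_dataset`.
#' @param protocol fitting protocol.
#' @param config base [fit_config()]; each restart offsets its seed.
#' @param n_restarts GA restarts per variant.
#' @return list with `results` (data.frame: variant, restart, seed,
#'   fitness), `best` (best fitness per variant, ranked) and `fits`
#'   (best run_ga result per variant).
#' @export
compare_models <- function(variants, dataset,
                           protocol = canonical_protocol(
                             conversion_hours = 120),
                           config = fit_config(), n_restarts = 3) {
  stopifnot(length(variants) >= 1, !is.null(names(variants)))
  rows <- list(); fits <- list()
  for (v in names(variants)) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      cfg <- config
      cfg$seed <- config$seed + 101L * (r - 1L) +
        10007L * (match(v, names(variants)) - 1L)
      res <- run_ga(variants[[v]], dataset, protocol, cfg)
      rows[[length(rows) + 1]] <- data.frame(
        variant = v, restart = r, seed = cfg$seed,
        fitness = res$best_fitness, stringsAsFactors = FALSE)
      if (is.null(best) || res$best_fitness > best$best_fitness)
        best <- res
    }
    fits[[v]] <- best
  }
  results <- do.call(rbind, rows)
  best <- vapply(split(results$fitness, results$variant), max, numeric(1))
  best <- sort(best, decreasing = TRUE)
  list(results = results, best = best, fits = fits)
}

#' Embed a simpler model's parameters into a larger topology
#'
#' Maps a fitted parameter set onto a topology that extends the original
#' by added edges, neutralising every addition: added edges get a very
#' large dissociation constant (their term is ~0 at physiological
#' concentrations), and a node that thereby gains its first activator --
#' and with it a background term -- has its `beta` set to `beta_fill`
#' with the exact reduction change of variables applied in reverse
#' (`alpha` scaled by `(1+beta)/beta`, each inhibitor `k` divided by
#' `(1+beta)^(1/h)`), so the embedded model's rate laws equal the
#' original's up to the negligible added-edge term.  Used to seed
#' genetic-algorithm runs of complex variants from fits of simpler ones.
#'
#' @param params fitted parameters for `from`.
#' @param from the simpler `grn_topology`.
#' @param to a `grn_topology` whose edge set extends `from`'s.
#' @param k_fill dissociation constant given to added edges.
#' @param h_fill Hill exponent given to added edges.
#' @param beta_fill background value given to newly beta-flagged nodes.
#' @return a `grn_params` vector for `to`.
#' @export
embed_params <- function(params, from, to, k_fill = 1e4, h_fill = 1,
                         beta_fill = 1) {
  stopifnot(setequal(from$nodes, to$nodes))
  old_keys <- edge_key(from$edges$source, from$edges$target)
  new_e <- to$edges
  new_keys <- edge_key(new_e$source, new_e$target)
  if (!all(old_keys %in% new_keys))
    stop("'to' must contain every edge of 'from'")
  p <- as.list(unclass(params))
  added <- setdiff(new_keys, old_keys)
  for (key in added) {
    p[[paste0("k_", key)]] <- k_fill
    p[[paste0("h_", key)]] <- h_fill
  }
  for (node in setdiff(to$beta_nodes, from$beta_nodes)) {
    B <- beta_fill
    p[[paste0("beta_", node)]] <- B
    p[[paste0("alpha_", node)]] <- p[[paste0("alpha_", node)]] *
      (1 + B) / B
    inh <- topology_edges(from, target = node, sign = INHIBITION)
    for (i in seq_len(nrow(inh))) {
      key <- edge_key(inh$source[i], node)
      h <- p[[paste0("h_", key)]]
      p[[paste0("k_", key)]] <- p[[paste0("k_", key)]] /
        (1 + B)^(1 / h)
    }
  }
  grn_params(unlist(p), to)
}
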