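# Shared fixture builders: construct participants/groups from plain lists of
# hex responses, via the public ingestion path.

# responses: named list, symbol -> character vector of hex codes (NA = missing)
make_trial_df <- function(responses, id = "p1") {
  do.call(rbind, lapply(names(responses), function(sym) {
    data.frame(
      participant_id = id,
      symbol = sym,
      response_color = responses[[sym]],
      stringsAsFactors = FALSE
    )
  }))
}

make_participant <- function(responses, id = "p1", trials_per_symbol = NULL,
                             color_space = "Luv") {
  if (is.null(trials_per_symbol)) {
    trials_per_symbol <- max(lengths(responses))
  }
  grp <- build_group(make_trial_df(responses, id),
                     trials_per_symbol = trials_per_symbol,
                     color_space = color_space)
  get_participant(grp, id)
}

make_grapheme <- function(hex, symbol = "A") {
  make_participant(stats::setNames(list(hex), symbol))$graphemes[[symbol]]
}

# Brute-force DBSCAN oracle: core points from neighborhood counts, clusters as
# connected components of the core-core eps-graph (transitive closure), noise
# as non-core points with no core neighbor. Border points are ambiguous by
# construction and checked separately.
oracle_dbscan <- function(points, eps, min_pts) {
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  adj <- unname(d <= eps)
  core <- unname(rowSums(adj) >= min_pts)
  # reachability among core points via boolean closure
  reach <- adj & outer(core, core, `&`)
  diag(reach) <- core
  repeat {
    nxt <- reach | ((reach %*% reach) > 0)
    if (identical(nxt, reach > 0)) break
    reach <- nxt
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(comp[i])) next
    members <- which(reach[i, ] > 0)
    comp[members] <- k
    k <- k + 1L
  }
  has_core_neighbor <- vapply(seq_len(n), function(i) any(adj[i, ] & core),
                              logical(1))
  list(core = core, comp = comp, noise = !core & !has_core_neighbor,
       adj = adj)
}
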