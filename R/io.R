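#' Export a network as an edge-list CSV or GraphML file
#'
#' @param net a [nidm_network].
#' @param file output path.
#' @return The path, invisibly.
#' @export
export_edgelist_csv <- function(net, file) {
  el <- edge_list(net)
  utils::write.csv(as.data.frame(el), file, row.names = FALSE)
  invisible(file)
}

#' @rdname export_edgelist_csv
#' @export
export_graphml <- function(net, file) {
  igraph::write_graph(as_igraph(net), file, format = "graphml")
  invisible(file)
}

#' Read a network back from an edge-list CSV
#'
#' @param file path written by [export_edgelist_csv()].
#' @param n number of nodes (defaults to the largest id in the file).
#' @return A [nidm_network].
#' @export
read_edgelist_csv <- function(file, n = NULL) {
  el <- utils::read.csv(file)
  if (is.null(n)) n <- max(el)
  nidm_network(n, as.matrix(el))
}

# participant table of one game: participant ids are ranks in the sorted
# score vector; the staircase position is the nearest position implied by
# the score's linear inversion
participant_table <- function(game) {
  scores <- game$scores
  rk <- rank(scores, ties.method = "first")
  asg <- game$assignment
  node_of_rank <- asg$node[match(seq_along(scores), asg$score_rank)]
  data.frame(
    participant_id = seq_along(scores),
    node_id = node_of_rank[rk],
    risk_score = scores,
    staircase_position = pmin(32L, pmax(1L, round(32 - 31 * scores / 2)))
  )
}

#' Write the three data categories of a batch (or list of games)
#'
#' Serializes results into the model's standard schemas:
#' `network.csv` lists, per game and round, every directed edge occurrence
#' of the round-start network (both orientations per undirected tie) plus a
#' row with an empty partner for isolated nodes; `decisions.csv` holds one
#' row per decision with its stage, type, action and perceived utility
#' delta; `participants.csv` maps participants (identified within a
#' session) to their node ids, risk scores and implied staircase positions.
#' A `metrics.json` file collects per-game summary metrics.
#'
#' @param results a `nidm_batch`, a single `nidm_game` or a list of games.
#' @param directory output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_outputs <- function(results, directory) {
  games <- if (inherits(results, "nidm_batch")) results$games
    else if (inherits(results, "nidm_game")) list(results)
    else results
  if (is.null(games) || !length(games)) stop("no games to write")
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", directory)

  network_rows <- list(); decision_rows <- list(); part_rows <- list()
  metrics <- list()
  for (g in games) {
    sid <- g$condition$session_index
    gid <- g$condition$game_index
    for (r in seq_len(g$rounds_played)) {
      el <- g$snapshots[[r]]
      st <- g$states[[r]]
      n <- length(st)
      from <- c(el[, 1L], el[, 2L])
      to <- c(el[, 2L], el[, 1L])
      isolated <- setdiff(seq_len(n), unique(from))
      network_rows[[length(network_rows) + 1L]] <- data.frame(
        session_id = sid, game_id = gid,
        clustering_setting = g$condition$clustering,
        mixing_setting = g$condition$mixing,
        round = r,
        node_id = c(from, isolated),
        disease_state = st[c(from, isolated)],
        connected_node_id = c(to, rep(NA_integer_, length(isolated)))
      )
    }
    d <- g$decisions
    decision_rows[[length(decision_rows) + 1L]] <- data.frame(
      session_id = sid, game_id = gid,
      round = d$round, ego_id = d$ego, alter_id = d$alter,
      offer_type = d$kind, decision = d$action, stage = d$stage,
      perceived_delta = d$perceived_delta
    )
    pt <- participant_table(g)
    names(pt)[names(pt) == "node_id"] <- paste0("node_id_game", gid)
    pt$session_id <- sid
    part_rows[[paste(sid, gid)]] <- pt
    metrics[[sprintf("session%d_game%d", sid, gid)]] <- list(
      clustering_setting = g$condition$clustering,
      mixing_setting = g$condition$mixing,
      seed = g$seed,
      rounds_played = g$rounds_played,
      final_size = g$final_size,
      ever_infected = length(g$ever_infected),
      final_clustering = network_clustering(g$final_net),
      final_mean_degree = mean_degree(g$final_net)
    )
  }

  utils::write.csv(do.call(rbind, network_rows),
                   file.path(directory, "network.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, decision_rows),
                   file.path(directory, "decisions.csv"), row.names = FALSE)

  # merge the per-session participant tables (one row per participant,
  # node ids of both games side by side when available)
  sessions <- unique(vapply(games, function(g) g$condition$session_index,
                            integer(1)))
  merged <- lapply(sessions, function(s) {
    tabs <- part_rows[grepl(paste0("^", s, " "), names(part_rows))]
    out <- tabs[[1L]]
    if (length(tabs) > 1L) {
      for (t2 in tabs[-1L]) {
        extra <- setdiff(names(t2), names(out))
        out <- cbind(out, t2[, extra, drop = FALSE])
      }
    }
    for (col in c("node_id_game1", "node_id_game2"))
      if (!col %in% names(out)) out[[col]] <- NA_integer_
    out[, c("session_id", "participant_id", "node_id_game1",
            "node_id_game2", "risk_score", "staircase_position")]
  })
  utils::write.csv(do.call(rbind, merged),
                   file.path(directory, "participants.csv"),
                   row.names = FALSE)
  jsonlite::write_json(metrics, file.path(directory, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(directory)
}
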