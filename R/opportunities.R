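#' Stage-1 opportunity selection
#'
#' Selects the alters offered to an ego this round. The number offered is
#' `round(phi * n)` (12 in the 60-node game). Each slot first draws a tier
#' with probabilities `(psi, xi, 1 - psi - xi)` over current neighbors,
#' neighbors of neighbors (excluding neighbors and the ego) and all other
#' nodes, so offers are on average 50% neighbors, 30% second neighbors and
#' 20% others under the defaults. Within the drawn tier, with probability
#' `omega` the not-yet-offered node most similar in risk-aversion score is
#' picked (ties to the lowest id), otherwise a uniform draw. When a tier
#' runs out of unoffered members the slot falls through in the cyclic order
#' neighbor, second neighbor, other. Uses the global RNG.
#'
#' @param ego the deciding node.
#' @param net a [nidm_network].
#' @param p a [nidm_params] object.
#' @param scores risk-aversion scores (defaults to those stored in `net`);
#'   only consulted when `omega > 0`.
#' @return Integer vector of distinct alters, never containing the ego. If
#'   fewer than `round(phi * n)` other nodes exist, all of them are offered.
#' @export
select_opportunities <- function(ego, net, p = nidm_params(),
                                 scores = net$score) {
  ego <- check_node(net, ego)
  n <- n_nodes(net)
  n_offer <- round(p$phi * n)
  if (n - 1L <= n_offer) return(setdiff(seq_len(n), ego))

  nb <- which(net$adj[ego, ])
  non <- setdiff(which(colSums(net$adj[nb, , drop = FALSE]) > 0L),
                 c(nb, ego))
  other <- setdiff(seq_len(n), c(nb, non, ego))
  tiers <- list(nb, non, other)

  if (p$omega > 0 && anyNA(scores))
    stop("omega > 0 requires complete risk scores")

  offered <- integer(0)
  for (slot in seq_len(n_offer)) {
    t0 <- sample.int(3L, 1L, prob = c(p$psi, p$xi, 1 - p$psi - p$xi))
    pick <- NA_integer_
    for (step in 0:2) {
      tier <- tiers[[(t0 - 1L + step) %% 3L + 1L]]
      avail <- setdiff(tier, offered)
      if (length(avail)) {
        if (p$omega > 0 && stats::runif(1) < p$omega) {
          d <- abs(scores[avail] - scores[ego])
          pick <- avail[which.min(d)] # lowest id among ties
        } else {
          pick <- avail[sample.int(length(avail), 1L)]
        }
        break
      }
    }
    offered <- c(offered, pick)
  }
  offered
}

#' Group stage-1 proposals into stage-2 decisions
#'
#' Proposals are ordered `(proposer, target)` pairs from stage 1. Reciprocal
#' proposals (both directions in the same round) establish mutual consent
#' immediately and are returned as automatically created ties without a
#' stage-2 decision. The remaining proposals are grouped by target into
#' accept-or-decline opportunities.
#'
#' @param proposals two-column matrix or data.frame of `(proposer, target)`
#'   pairs; may have zero rows.
#' @param net optional [nidm_network] used to reject proposals over an
#'   existing tie (a protocol violation).
#' @return A list with `auto_create` (two-column matrix of mutually proposed
#'   pairs, `from < to`) and `stage2` (data.frame with columns `ego` and
#'   `alter`: the target deciding about the proposer).
#' @export
collect_stage2_opportunities <- function(proposals, net = NULL) {
  if (is.null(proposals) || NROW(proposals) == 0L) {
    return(list(auto_create = matrix(integer(0), 0, 2,
                                     dimnames = list(NULL, c("from", "to"))),
                stage2 = data.frame(ego = integer(0), alter = integer(0))))
  }
  pr <- as.matrix(proposals)[, 1:2, drop = FALSE]
  storage.mode(pr) <- "integer"
  if (anyDuplicated(pr)) stop("duplicate proposal for an ordered pair")
  if (!is.null(net) && any(net$adj[pr]))
    stop("proposal over an existing tie (protocol violation)")
  key <- paste(pmin(pr[, 1L], pr[, 2L]), pmax(pr[, 1L], pr[, 2L]))
  reciprocal <- key %in% key[duplicated(key)]
  auto <- unique(cbind(from = pmin(pr[reciprocal, 1L], pr[reciprocal, 2L]),
                       to = pmax(pr[reciprocal, 1L], pr[reciprocal, 2L])))
  rest <- pr[!reciprocal, , drop = FALSE]
  stage2 <- data.frame(ego = rest[, 2L], alter = rest[, 1L])
  stage2 <- stage2[order(stage2$ego, stage2$alter), , drop = FALSE]
  rownames(stage2) <- NULL
  list(auto_create = auto, stage2 = stage2)
}
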