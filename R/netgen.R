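#' Structural targets of the baseline networks
#'
#' Both baselines have 60 nodes and 178 edges (mean degree 5.93 at printed
#' precision) and are connected; they differ in mean local clustering
#' (LO: 0.06, HI: 0.62) while keeping closeness nearly matched
#' (LO: about 0.975, HI: about 0.955).
#'
#' @param setting `"LO"` or `"HI"`.
#' @return A list with the targets and per-metric tolerances.
#' @export
network_spec <- function(setting = c("LO", "HI")) {
  setting <- match.arg(setting)
  list(
    n = 60L, edges = 178L,
    target_clustering = if (setting == "HI") 0.62 else 0.06,
    target_closeness = if (setting == "HI") 0.955 else 0.975,
    tol_clustering = 0.01,
    tol_closeness = 0.02,
    connected = TRUE
  )
}

# ---- LO: one sparse cluster -------------------------------------------
#
# 18 triangles arranged so that every triangle shares each of its three
# corners with exactly one other triangle (a 3-regular "triangle adjacency"
# circulant on 18 slots). The 27 corner nodes then sit in two edge-disjoint
# triangles each (local proportion 2/15); with 27 * 2/15 = 3.6 the mean over
# 60 nodes is exactly 0.06. The remainder is filled triangle-free: four
# degree-5 nodes share a common hub (which blocks mutually profitable tie
# creation among them), everything else reaches degree 6. All 60 nodes are
# pairwise-stable under the no-disease utility with alpha = 0.
lo_skeleton <- function() {
  edges <- list()
  tri_member <- function(t) {
    c(((t - 2L) %% 18L) + 1L,                 # shared corner with triangle t-1
      t,                                       # shared corner with triangle t+1
      18L + ((t - 1L) %% 9L) + 1L)             # shared corner with triangle t+9
  }
  for (t in 1:18) {
    m <- tri_member(t)
    edges[[length(edges) + 1L]] <- rbind(m[c(1, 2)], m[c(1, 3)], m[c(2, 3)])
  }
  hub <- 28L; low <- 29:32
  edges[[length(edges) + 1L]] <- cbind(hub, low)
  el <- do.call(rbind, edges)
  deficit <- integer(60)
  deficit[1:27] <- 2L   # triangle corners: 4 triangle edges + 2 fillers
  deficit[hub] <- 2L    # hub: 4 spokes + 2 fillers
  deficit[low] <- 4L    # degree-5 nodes: hub spoke + 4 fillers
  deficit[33:60] <- 6L
  list(edges = el, deficit = deficit)
}

# ---- HI: several dense clusters ---------------------------------------
#
# Nine 6-cliques; fifty clique members carry exactly one external tie
# (local proportion 10/15 = 2/3), four members of one clique carry none
# (degree 5, proportion 1), and six "connector" nodes tie into six distinct
# cliques each (proportion 0). Mean clustering (50 * 2/3 + 4) / 60 = 0.6222
# prints as 0.62. External ties split into 36 connector edges and 7
# clique-to-clique bridges.
hi_skeleton <- function() {
  comm <- split(1:54, rep(1:9, each = 6L))
  el <- do.call(rbind, lapply(comm, function(m) t(utils::combn(m, 2L))))
  list(edges = el, comm = comm, connectors = 55:60,
       special = 9L, pure = comm[[9]][3:6])
}

# add filler edges subject to: simple graph, and no common neighbor between
# the endpoints (so no triangle beyond design ever appears). Returns NULL
# when the random completion jams.
fill_triangle_free <- function(adj, deficit) {
  n <- nrow(adj)
  guard <- 0L
  while (any(deficit > 0L)) {
    guard <- guard + 1L
    if (guard > 10000L) return(NULL)
    u <- which(deficit == max(deficit))
    u <- u[sample.int(length(u), 1L)]
    cand <- which(deficit > 0L & !adj[u, ] & seq_len(n) != u)
    if (length(cand)) {
      common <- as.vector(adj[cand, , drop = FALSE] %*% adj[u, ])
      cand <- cand[common == 0L]
    }
    if (!length(cand)) return(NULL)
    v <- cand[sample.int(length(cand), 1L)]
    adj[u, v] <- adj[v, u] <- TRUE
    deficit[c(u, v)] <- deficit[c(u, v)] - 1L
  }
  adj
}

build_lo <- function() {
  sk <- lo_skeleton()
  adj <- matrix(FALSE, 60, 60)
  adj[sk$edges] <- TRUE
  adj[sk$edges[, 2:1]] <- TRUE
  fill_triangle_free(adj, sk$deficit)
}

build_hi <- function() {
  sk <- hi_skeleton()
  adj <- matrix(FALSE, 60, 60)
  adj[sk$edges] <- TRUE
  adj[sk$edges[, 2:1]] <- TRUE

  # connector-community incidence: every connector joins 6 of the 8
  # non-special cliques; community quotas 4 or 5 keep the count at 36
  repeat {
    quota <- sample(c(rep(5L, 4L), rep(4L, 4L)))
    inc <- matrix(FALSE, 6L, 8L)
    ok <- TRUE
    for (k in 1:6) {
      open <- which(quota > 0L)
      if (length(open) < 6L) { ok <- FALSE; break }
      pick <- open[order(-quota[open], stats::runif(length(open)))][1:6]
      inc[k, pick] <- TRUE
      quota[pick] <- quota[pick] - 1L
    }
    if (ok && all(quota == 0L)) break
  }

  # within each non-special clique, pick which members host connector edges
  # versus bridges (each member has exactly one external tie)
  bridge_slots <- integer(0)
  for (c_ in 1:8) {
    members <- sample(sk$comm[[c_]])
    n_conn <- sum(inc[, c_])
    conn_members <- members[seq_len(n_conn)]
    ks <- which(inc[, c_])
    for (j in seq_along(ks)) {
      u <- sk$connectors[ks[j]]; v <- conn_members[j]
      adj[u, v] <- adj[v, u] <- TRUE
    }
    bridge_slots <- c(bridge_slots, members[-seq_len(n_conn)])
  }
  # two bridge endpoints in the special clique
  bridge_slots <- c(bridge_slots, sk$comm[[sk$special]][1:2])

  # pair the 14 bridge endpoints across different cliques
  comm_of <- rep(1:9, each = 6L)
  for (try in 1:200) {
    perm <- sample(bridge_slots)
    pairs <- matrix(perm, ncol = 2L, byrow = TRUE)
    if (all(comm_of[pairs[, 1L]] != comm_of[pairs[, 2L]])) {
      for (k in seq_len(nrow(pairs)))
        adj[pairs[k, 1L], pairs[k, 2L]] <-
          adj[pairs[k, 2L], pairs[k, 1L]] <- TRUE
      return(adj)
    }
  }
  NULL
}

adj_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n); seen[1L] <- TRUE; frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0L & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Generate a baseline network
#'
#' Constructs the low- or high-clustering 60-node baseline: 178 edges (mean
#' degree 5.93), connected, with mean local clustering 0.06 (`"LO"`) or 0.62
#' (`"HI"`), built so that every node starts at a pairwise-stable optimum of
#' the no-disease utility — no node gains from dissolving a tie, and no two
#' consenting nodes gain from creating one. Construction is a seeded
#' deterministic design (triangle chains plus triangle-free fill for LO;
#' 6-cliques plus connectors and bridges for HI) followed, only if a target
#' is missed, by degree-preserving edge swaps towards the clustering target.
#' Node labels are randomly permuted, so different seeds give different
#' edge sets with identical structure.
#'
#' @param setting `"LO"` or `"HI"`.
#' @param seed integer seed; the same seed reproduces the same network.
#' @param p a [nidm_params] object used for the equilibrium report
#'   (`alpha` is taken from the setting, not from `p`).
#' @param report_equilibrium compute and attach the equilibrium fraction
#'   (skippable because it costs a full pairwise [tie_delta()] scan).
#' @return A [nidm_network] with attributes `setting`, `seed` and
#'   `equilibrium_fraction` (share of nodes at a local utility optimum).
#' @export
generate_baseline <- function(setting = c("LO", "HI"), seed = 1L,
                              p = nidm_params(), report_equilibrium = TRUE) {
  setting <- match.arg(setting)
  spec <- network_spec(setting)
  set.seed(as.integer(seed))
  adj <- NULL
  for (attempt in 1:500) {
    adj <- if (setting == "LO") build_lo() else build_hi()
    if (!is.null(adj) && adj_connected(adj)) break
    adj <- NULL
  }
  if (is.null(adj))
    stop("baseline construction failed to produce a connected network")

  perm <- sample.int(60L)
  adj <- adj[perm, perm]

  net <- nidm_network(60L)
  net$adj <- adj

  if (abs(network_clustering(net) - spec$target_clustering) >
      spec$tol_clustering) {
    net <- refine_by_swaps(net, spec)
    if (abs(network_clustering(net) - spec$target_clustering) >
        spec$tol_clustering)
      stop(sprintf(
        "swap search missed the clustering target (best %.4f, target %.2f)",
        network_clustering(net), spec$target_clustering))
  }

  attr(net, "setting") <- setting
  attr(net, "seed") <- as.integer(seed)
  if (report_equilibrium) {
    eq_p <- p
    eq_p$alpha <- condition_alpha(setting)
    attr(net, "equilibrium_fraction") <- equilibrium_fraction(net, eq_p)
  }
  net
}

# Degree-preserving swap search towards the clustering target: repeatedly
# exchange the endpoints of two random edges, accepting swaps that reduce
# the deviation while keeping the graph simple and connected.
refine_by_swaps <- function(net, spec, iterations = 20000L) {
  best <- abs(network_clustering(net) - spec$target_clustering)
  for (it in seq_len(iterations)) {
    if (best <= spec$tol_clustering / 2) break
    el <- edge_list(net)
    k <- sample.int(nrow(el), 2L)
    a <- el[k[1L], ]; b <- el[k[2L], ]
    u <- a[1L]; v <- a[2L]; x <- b[1L]; y <- b[2L]
    if (length(unique(c(u, v, x, y))) < 4L) next
    if (net$adj[u, y] || net$adj[x, v]) next
    cand <- remove_edge(remove_edge(net, u, v), x, y)
    cand <- add_edge(add_edge(cand, u, y), x, v)
    dev <- abs(network_clustering(cand) - spec$target_clustering)
    if (dev < best && adj_connected(cand$adj)) {
      net <- cand
      best <- dev
    }
  }
  net
}

#' Fraction of nodes at a local utility optimum
#'
#' A node is at a local optimum (pairwise-stable position) when no single
#' tie change available to it improves its no-disease utility: dissolving
#' any existing tie does not help, and no tie creation exists that both the
#' node and the prospective partner would profit from (creation requires
#' mutual consent in the game).
#'
#' @param net a [nidm_network].
#' @param p a [nidm_params] object; set `alpha` to the triad preference of
#'   the setting under scrutiny. Missing risk scores are treated as
#'   risk-neutral (irrelevant without disease).
#' @return The fraction of nodes with no improving move, in `[0, 1]`.
#' @export
equilibrium_fraction <- function(net, p = nidm_params()) {
  n <- n_nodes(net)
  if (anyNA(net$score)) net$score <- rep(1, n)
  deltas <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    deltas[i, j] <- tie_delta(net, i, j, p)
  stable <- vapply(seq_len(n), function(i) {
    nb <- which(net$adj[i, ])
    if (any(deltas[i, nb] < 0)) return(FALSE)
    non <- setdiff(which(!net$adj[i, ]), i)
    !any(deltas[i, non] > 0 & deltas[cbind(non, i)] > 0)
  }, logical(1))
  mean(stable)
}

#' Assign risk-scored participants to network positions
#'
#' Scores are first sorted ascending and then mapped onto a fixed,
#' deterministic node ordering. Under assortative mixing (`"AS"`) the
#' ordering preserves locality — a spectral (Fiedler-vector) ordering
#' sharpened by swap descent, which lines cliques up contiguously in the
#' high-clustering network — so neighbors receive similar ranks. Under
#' random mixing (`"RA"`) ranks are spread along the same ordering with a
#' low-discrepancy (golden-ratio) scrambling, so neighboring ranks carry
#' unrelated scores.
#'
#' @param net a [nidm_network].
#' @param scores numeric vector, one score per node.
#' @param mixing `"RA"` or `"AS"`.
#' @return The network with scores assigned; the node-to-rank map is
#'   attached as attribute `assignment`.
#' @export
assign_participants <- function(net, scores, mixing = c("RA", "AS")) {
  mixing <- match.arg(mixing)
  n <- n_nodes(net)
  if (length(scores) != n) stop("need exactly one score per node")
  ord <- locality_ordering(net)        # ord[j] = node at locality position j
  sorted <- sort(scores)
  rank_at_pos <- if (mixing == "AS") seq_len(n) else scramble_ranks(n)
  sc <- numeric(n)
  sc[ord] <- sorted[rank_at_pos]
  net$score <- sc
  attr(net, "assignment") <- data.frame(
    node = ord, position = seq_len(n), score_rank = rank_at_pos
  )
  net
}

# 1-D locality ordering: Fiedler vector of the graph Laplacian, improved by
# greedy position swaps minimizing the summed squared rank distance over
# edges. Deterministic for a given network.
locality_ordering <- function(net) {
  n <- n_nodes(net)
  A <- net$adj * 1
  L <- diag(rowSums(A)) - A
  ev <- eigen(L, symmetric = TRUE)
  f <- ev$vectors[, n - 1L]
  pos <- integer(n)
  pos[order(f, seq_len(n))] <- seq_len(n)   # pos[node] = rank along f
  nbs <- lapply(seq_len(n), function(i) which(net$adj[i, ]))
  node_cost <- function(i, pos) sum((pos[i] - pos[nbs[[i]]])^2)
  improved <- TRUE; sweep <- 0L
  while (improved && sweep < 25L) {
    improved <- FALSE; sweep <- sweep + 1L
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      before <- node_cost(i, pos) + node_cost(j, pos)
      cand <- pos
      cand[c(i, j)] <- pos[c(j, i)]
      after <- node_cost(i, cand) + node_cost(j, cand)
      if (after < before - 1e-9) {
        pos <- cand; improved <- TRUE
      }
    }
  }
  order(pos)  # node at each position
}

# fixed low-discrepancy permutation of 1..n (golden-ratio scrambling)
scramble_ranks <- function(n) {
  phi <- (sqrt(5) - 1) / 2
  order(order((seq_len(n) * phi) %% 1))
}

#' Sample risk-aversion scores
#'
#' Draws from a normal distribution with mean 1.27 and standard deviation
#' 0.45, truncated to the open interval `(0, 2)` — the score distribution
#' used to endow simulated agents, mirroring the empirical staircase-task
#' scores rescaled to the model range. Uses the global RNG.
#'
#' @param n number of scores.
#' @param mean,sd parameters of the untruncated normal.
#' @return Numeric vector of length `n`, all values strictly inside
#'   `(0, 2)`.
#' @export
sample_risk_scores <- function(n, mean = 1.27, sd = 0.45) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw > 0 & draw < 2])
  }
  out[seq_len(n)]
}
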