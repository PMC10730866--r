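#' Point rewards for the number of relations
#'
#' The relation component of the round utility: benefits `b1 * t` minus the
#' marginally increasing costs `c1 * t + c2 * t^2`, multiplied by the point
#' scaling factor. Under the defaults the term is maximal at six relations
#' (100 points) and, with the default clamp, never turns negative however
#' many relations a node holds.
#'
#' @param t number of relations (nonnegative integer).
#' @param p a [nidm_params] object.
#' @return Points per round (unrounded).
#' @examples
#' p <- nidm_params()
#' round(relation_points(6, p)) # 100
#' relation_points(12, p)       # clamped to 0
#' @export
relation_points <- function(t, p = nidm_params()) {
  p$scale * relation_value(t, p)
}

# unscaled relation utility, clamp applied per parameter flag
relation_value <- function(t, p) {
  if (any(t < 0) || any(t != floor(t))) stop("'t' must be a nonnegative integer")
  v <- p$b1 * t - (p$c1 * t + p$c2 * t^2)
  if (p$clamp_relation_reward) v <- pmax(0, v)
  v
}

#' Point rewards for triadic closure
#'
#' The triad component of the round utility:
#' `scale * b2 * (1 - 2 |x - alpha| / max(alpha, 1 - alpha))`, maximal when
#' the proportion of closed triads `x` equals the preferred proportion
#' `alpha` and linearly decreasing on each side. Unlike the relation term it
#' is not floored at zero, so proportions far from the preference cost
#' points.
#'
#' @param x proportion of closed triads, in `[0, 1]`.
#' @param p a [nidm_params] object.
#' @return Points per round (unrounded).
#' @examples
#' round(triad_points(0, nidm_params(alpha = 0))) # 21
#' @export
triad_points <- function(x, p = nidm_params()) {
  p$scale * triad_value(x, p)
}

triad_value <- function(x, p) {
  if (any(x < 0) || any(x > 1)) stop("'x' must lie in [0, 1]")
  p$b2 * (1 - 2 * abs(x - p$alpha) / max(p$alpha, 1 - p$alpha))
}

#' Infection penalty
#'
#' Points deducted per round of infection: `scale * sigma` (about 14 points
#' under the defaults) for state `"I"`, zero for susceptible and recovered
#' nodes.
#'
#' @param state disease state, one of `"S"`, `"I"`, `"R"`.
#' @param p a [nidm_params] object.
#' @return Nonnegative points to subtract.
#' @export
infection_penalty <- function(state, p = nidm_params()) {
  if (!all(state %in% c("S", "I", "R"))) stop("invalid disease state")
  ifelse(state == "I", p$scale * p$sigma, 0)
}

#' Realized round reward of a node
#'
#' Stage-3 points: relation and triad rewards for the node's current network
#' position minus the infection penalty. Realized rewards always use the
#' objective severity `sigma`; risk perception only enters decision
#' utilities.
#'
#' @param net a [nidm_network].
#' @param i node id.
#' @param p a [nidm_params] object.
#' @return A `reward_breakdown` list with components `relation_points`,
#'   `triad_points`, `infection_penalty` and `total`.
#' @export
round_reward <- function(net, i, p = nidm_params()) {
  i <- check_node(net, i)
  rel <- relation_points(sum(net$adj[i, ]), p)
  tri <- triad_points(local_triad_proportion(net, i), p)
  pen <- infection_penalty(net$state[i], p)
  structure(
    list(relation_points = rel, triad_points = tri,
         infection_penalty = pen, total = rel + tri - pen),
    class = "reward_breakdown"
  )
}

#' @export
print.reward_breakdown <- function(x, ...) {
  cat(sprintf("<reward_breakdown> relations %.2f + triads %.2f - infection %.2f = %.2f points\n",
              x$relation_points, x$triad_points, x$infection_penalty, x$total))
  invisible(x)
}

#' Perceived cost of infection
#'
#' The risk-perception transformation of the infection penalty used in
#' decision utilities: severity and infection probability are raised to
#' powers of the risk-aversion score `r`, `w * sigma^r * pi^(2 - r)`, in
#' unscaled utility units. At `r = 1` this reduces to the risk-neutral
#' expected cost `sigma * pi`; higher `r` amplifies both perceived severity
#' and perceived probability.
#'
#' @param r risk-aversion score, in the open interval `(0, 2)`.
#' @param pi probability of getting infected this round, in `[0, 1]`.
#' @param p a [nidm_params] object (`sigma` and `ext_risk_weight` are used).
#' @return Nonnegative unscaled cost.
#' @examples
#' perceived_infection_cost(1, 0.15) # 0.051, risk neutral
#' @export
perceived_infection_cost <- function(r, pi, p = nidm_params()) {
  if (any(r <= 0) || any(r >= 2)) stop("'r' must lie in the open interval (0, 2)")
  if (any(pi < 0) || any(pi > 1)) stop("'pi' must lie in [0, 1]")
  p$ext_risk_weight * p$sigma^r * pi^(2 - r)
}
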