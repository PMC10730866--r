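#' Model parameters
#'
#' Bundles every constant of the networking-game model: utility weights for
#' social relations and triadic closure, infection severity and transmission
#' probability, recovery time, the opportunity-selection mixture, the
#' similarity weight used for assortative offer selection, the point scaling
#' factor, and the behavioural extension switches.
#'
#' Defaults reproduce the experiment's settings: six relations are the
#' optimum of the relation term (worth 100 points once scaled), the triad
#' term pays up to `scale * b2` (about 21 points), and each infected round
#' costs `scale * sigma` (about 14 points).
#'
#' @param b1 benefit weight per social relation.
#' @param b2 weight of the triad-closure term.
#' @param c1 linear cost per relation.
#' @param c2 quadratic cost per relation.
#' @param alpha preferred proportion of closed triads, in `[0, 1]`.
#'   0 in the low-clustering setting, 0.67 in the high-clustering setting.
#' @param sigma unscaled cost of being infected per round.
#' @param gamma per-neighbor transmission probability, in `[0, 1]`.
#' @param tau recovery time in rounds (positive integer).
#' @param phi fraction of the network offered to each ego per round.
#' @param psi probability that an offered slot targets a neighbor.
#' @param xi probability that an offered slot targets a neighbor of a
#'   neighbor.
#' @param omega probability of a similarity-based pick within a tier, in
#'   `[0, 1]`. 0 under random mixing, 0.8 under assortative mixing.
#' @param scale point scaling factor. The canonical value 41.88 reproduces
#'   the advertised 100 / 21 / 14 point rewards; 41.55 is accepted as an
#'   alternative.
#' @param max_rounds maximum number of rounds per game.
#' @param clamp_relation_reward if `TRUE` (default), negative relation
#'   rewards are floored at zero so that holding many relations never costs
#'   points.
#' @param ext_risk_weight nonnegative weight multiplying the perceived
#'   infection cost (behavioural extension; 1 = original model).
#' @param ext_p_reward_seeking probability that a decision is made to
#'   increase point rewards; with the complementary probability (and a
#'   non-infected alter) the agent picks uniformly between the two actions.
#' @param ext_penalty_all_egos if `TRUE`, infected and recovered egos also
#'   incur the perceived infection cost in their decision utilities.
#'
#' @return An object of class `nidm_params` (a validated list).
#' @examples
#' p <- nidm_params()
#' relation_points(6, p) # about 100 points
#' @export
nidm_params <- function(b1 = 1.0, b2 = 0.5, c1 = 0.2, c2 = 0.067,
                        alpha = 0.0, sigma = 0.34, gamma = 0.15,
                        tau = 4L, phi = 0.2, psi = 0.5, xi = 0.3,
                        omega = 0.0, scale = 41.88, max_rounds = 20L,
                        clamp_relation_reward = TRUE,
                        ext_risk_weight = 1.0,
                        ext_p_reward_seeking = 1.0,
                        ext_penalty_all_egos = FALSE) {
  p <- list(
    b1 = b1, b2 = b2, c1 = c1, c2 = c2, alpha = alpha, sigma = sigma,
    gamma = gamma, tau = as.integer(tau), phi = phi, psi = psi, xi = xi,
    omega = omega, scale = scale, max_rounds = as.integer(max_rounds),
    clamp_relation_reward = isTRUE(clamp_relation_reward),
    ext_risk_weight = ext_risk_weight,
    ext_p_reward_seeking = ext_p_reward_seeking,
    ext_penalty_all_egos = isTRUE(ext_penalty_all_egos)
  )
  class(p) <- "nidm_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  for (nm in c("gamma", "phi", "psi", "xi", "omega", "alpha",
               "ext_p_reward_seeking")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a single probability in [0, 1]", nm))
  }
  if (p$psi + p$xi > 1 + 1e-12)
    stop("'psi' + 'xi' must not exceed 1")
  if (p$tau < 1L) stop("'tau' must be a positive integer")
  if (p$max_rounds < 1L) stop("'max_rounds' must be a positive integer")
  if (p$scale <= 0) stop("'scale' must be positive")
  if (p$ext_risk_weight < 0) stop("'ext_risk_weight' must be nonnegative")
  if (max(p$alpha, 1 - p$alpha) <= 0) stop("'alpha' is degenerate")
  invisible(p)
}

#' @export
print.nidm_params <- function(x, ...) {
  cat("<nidm_params>\n")
  cat(sprintf("  utility: b1=%.3g b2=%.3g c1=%.3g c2=%.3g alpha=%.3g scale=%.4g\n",
              x$b1, x$b2, x$c1, x$c2, x$alpha, x$scale))
  cat(sprintf("  disease: sigma=%.3g gamma=%.3g tau=%d\n",
              x$sigma, x$gamma, x$tau))
  cat(sprintf("  offers:  phi=%.3g psi=%.3g xi=%.3g omega=%.3g\n",
              x$phi, x$psi, x$xi, x$omega))
  cat(sprintf("  game:    max_rounds=%d clamp_relation_reward=%s\n",
              x$max_rounds, x$clamp_relation_reward))
  cat(sprintf("  ext:     risk_weight=%.3g p_reward_seeking=%.3g penalty_all_egos=%s\n",
              x$ext_risk_weight, x$ext_p_reward_seeking, x$ext_penalty_all_egos))
  invisible(x)
}

#' Experimental condition
#'
#' One cell of the two-by-two design: baseline clustering (`"LO"` single
#' sparse cluster with `alpha = 0`, or `"HI"` several dense clusters with
#' `alpha = 0.67`) crossed with social mixing (`"RA"` random, `omega = 0`;
#' `"AS"` assortative by risk-aversion score, `omega = 0.8`).
#'
#' @param clustering `"LO"` or `"HI"`.
#' @param mixing `"RA"` or `"AS"`.
#' @param session_index integer position of the session in the schedule.
#' @param game_index game within the session, 1 or 2.
#' @param seed integer seed driving every random draw of the game.
#' @return An object of class `nidm_condition`.
#' @seealso [session_plan()] for the alternation schedule, [run_game()].
#' @export
nidm_condition <- function(clustering = c("LO", "HI"),
                           mixing = c("RA", "AS"),
                           session_index = 1L, game_index = 1L,
                           seed = 1L) {
  clustering <- match.arg(clustering)
  mixing <- match.arg(mixing)
  if (!game_index %in% c(1L, 2L)) stop("'game_index' must be 1 or 2")
  structure(
    list(clustering = clustering, mixing = mixing,
         session_index = as.integer(session_index),
         game_index = as.integer(game_index),
         seed = as.integer(seed)),
    class = "nidm_condition"
  )
}

#' @export
print.nidm_condition <- function(x, ...) {
  cat(sprintf("<nidm_condition> %s:%s (session %d, game %d, seed %d)\n",
              x$clustering, x$mixing, x$session_index, x$game_index, x$seed))
  invisible(x)
}

# alpha / omega implied by a condition
condition_alpha <- function(clustering) if (clustering == "HI") 0.67 else 0.0
condition_omega <- function(mixing) if (mixing == "AS") 0.8 else 0.0
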