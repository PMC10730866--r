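#' Guaranteed reward offered in a staircase round
#'
#' The five-choice staircase risk-elicitation task offers, in every round, a
#' choice between a 50:50 gamble for 300 points and a guaranteed amount.
#' The first guaranteed amount is 160 points; each subsequent round bisects
#' with halving steps (80, 40, 20, 10): a gamble raises, a safe choice
#' lowers the next guaranteed amount. After a safe first choice round two
#' offers 80 points; after a gamble, 240.
#'
#' @param round_k round number, 1 to 5.
#' @param prior_choices logical vector of the choices already made
#'   (`TRUE` = gamble, `FALSE` = safe), of length `round_k - 1`.
#' @return The guaranteed amount in points.
#' @export
guaranteed_amount <- function(round_k, prior_choices = logical(0)) {
  if (!round_k %in% 1:5) stop("'round_k' must be between 1 and 5")
  if (length(prior_choices) != round_k - 1L)
    stop("need exactly one prior choice per completed round")
  amount <- 160
  for (j in seq_along(prior_choices)) {
    step <- 160 / 2^j
    amount <- amount + if (prior_choices[j]) step else -step
  }
  amount
}

#' Staircase position from a choice sequence
#'
#' The 32 possible five-choice sequences map bijectively onto positions 1
#' (always safe, most risk-averse) to 32 (always gamble, least
#' risk-averse): each gamble in round `k` adds `2^(5-k)`.
#'
#' @param choices logical vector of length 5 (`TRUE` = gamble).
#' @return Integer position in 1..32.
#' @export
choices_to_position <- function(choices) {
  if (length(choices) != 5L || anyNA(choices))
    stop("'choices' must be five TRUE/FALSE values")
  1L + sum(as.integer(choices) * 2L^(4:0))
}

#' Risk-aversion score from a staircase position
#'
#' Inverts and rescales the position linearly to `[0, 2]`, higher values
#' denoting higher risk aversion: position 1 maps to 2.0, position 32 to
#' 0.0.
#'
#' @param position integer in 1..32.
#' @return Score in `[0, 2]`.
#' @export
position_to_score <- function(position) {
  if (any(!position %in% 1:32)) stop("'position' must be in 1..32")
  2 * (32 - position) / 31
}

#' Full staircase record from a choice sequence
#'
#' @param choices logical vector of length 5 (`TRUE` = gamble).
#' @return A `staircase_record` list: the choices, the five guaranteed
#'   amounts offered, the terminal position and the risk-aversion score.
#' @export
staircase_record <- function(choices) {
  amounts <- vapply(1:5, function(k)
    guaranteed_amount(k, choices[seq_len(k - 1L)]), numeric(1))
  pos <- choices_to_position(choices)
  structure(
    list(choices = as.logical(choices), guaranteed_amounts = amounts,
         position = pos, score = position_to_score(pos)),
    class = "staircase_record"
  )
}

#' @export
print.staircase_record <- function(x, ...) {
  cat(sprintf("<staircase_record> choices %s | position %d | score %.3f\n",
              paste(as.integer(x$choices), collapse = ""),
              x$position, x$score))
  invisible(x)
}

#' Simulated staircase responder
#'
#' A deterministic responder for running full sessions without human input:
#' the agent gambles whenever the guaranteed amount falls below its
#' certainty equivalent of the 50:50 gamble for 300 points. The certainty
#' equivalent is derived from a power utility with exponent `2 - r_true`,
#' so a risk-neutral agent (`r_true = 1`) values the gamble at 150 points
#' and higher `r_true` lowers the threshold. The recovered score is a
#' weakly monotone function of `r_true`.
#'
#' @param r_true true risk-aversion parameter in the open interval `(0, 2)`.
#' @param noise_sd optional standard deviation of Gaussian noise added to
#'   the certainty equivalent before each choice (0 = deterministic).
#' @return A `staircase_record`.
#' @export
simulate_staircase <- function(r_true, noise_sd = 0) {
  if (r_true <= 0 || r_true >= 2) stop("'r_true' must lie in (0, 2)")
  rho <- 2 - r_true
  ce <- 300 * 0.5^(1 / rho)
  choices <- logical(5)
  for (k in 1:5) {
    offer <- guaranteed_amount(k, choices[seq_len(k - 1L)])
    thr <- ce + if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
    choices[k] <- offer < thr  # gamble when the sure amount is too low
  }
  staircase_record(choices)
}

#' Read or write staircase records as CSV rows
#'
#' @param records a list of `staircase_record` objects.
#' @param file path of the CSV file.
#' @return `write_staircase_csv` invisibly returns the data.frame written;
#'   `read_staircase_csv` returns a list of `staircase_record`s.
#' @export
write_staircase_csv <- function(records, file) {
  df <- do.call(rbind, lapply(records, function(r) {
    data.frame(
      c1 = as.integer(r$choices[1]), c2 = as.integer(r$choices[2]),
      c3 = as.integer(r$choices[3]), c4 = as.integer(r$choices[4]),
      c5 = as.integer(r$choices[5]),
      a1 = r$guaranteed_amounts[1], a2 = r$guaranteed_amounts[2],
      a3 = r$guaranteed_amounts[3], a4 = r$guaranteed_amounts[4],
      a5 = r$guaranteed_amounts[5],
      position = r$position, score = r$score
    )
  }))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}

#' @rdname write_staircase_csv
#' @export
read_staircase_csv <- function(file) {
  df <- utils::read.csv(file)
  lapply(seq_len(nrow(df)), function(k)
    staircase_record(as.logical(unlist(df[k, paste0("c", 1:5)]))))
}
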