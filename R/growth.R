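# Feeding-trial production indices: specific growth rate, food conversion
# ratio, relative food intake.

#' Specific growth rate (% per day)
#'
#' `SGR = (ln(final) - ln(initial)) / days * 100`.
#'
#' @param initial,final Body weights (g), > 0.
#' @param days Trial duration in days, > 0.
#' @return Percent weight gain per day. Vectorized.
#' @export
sgr <- function(initial, final, days) {
  if (any(initial <= 0) || any(final <= 0) || any(days <= 0))
    stop("weights and days must be positive")
  (log(final) - log(initial)) / days * 100
}

#' Food conversion ratio
#'
#' `FCR = food intake (g) / wet weight gain (g)`; lower is more efficient.
#'
#' @param feed_intake Dry-matter feed intake (g).
#' @param gain Wet weight gain (g), > 0.
#' @return The dimensionless ratio. Vectorized.
#' @export
fcr <- function(feed_intake, gain) {
  if (any(gain <= 0)) stop("gain must be positive")
  feed_intake / gain
}

#' Relative food intake (g per kg body weight per day)
#'
#' `RFI = daily food intake (g/day) / geometric mean body weight (kg)`,
#' with the geometric mean `sqrt(initial * final) / 1000` kg.
#'
#' @param daily_intake Daily food intake per fish (g/day).
#' @param initial,final Body weights (g), > 0.
#' @return Intake in g per kg body weight per day. Vectorized.
#' @export
rfi <- function(daily_intake, initial, final) {
  if (any(initial <= 0) || any(final <= 0))
    stop("weights must be positive")
  daily_intake / (sqrt(initial * final) / 1000)
}

#' Production indices for a table of growth records
#'
#' @param records Data.frame with columns `initial_weight`, `final_weight`,
#'   `days`, `feed_intake`, and optionally `daily_intake` (defaults to
#'   `feed_intake / days`) and `gain` (defaults to `final - initial`; when
#'   supplied independently it must agree with `final - initial` within
#'   0.01 g).
#' @return The records with `sgr`, `fcr`, `rfi` columns appended.
#' @export
growth_indices <- function(records) {
  req <- c("initial_weight", "final_weight", "days", "feed_intake")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("growth records missing column(s): ", paste(miss, collapse = ", "))
  gain <- records$final_weight - records$initial_weight
  if ("gain" %in% names(records)) {
    if (any(abs(records$gain - gain) >= 0.01, na.rm = TRUE))
      stop("supplied gain inconsistent with final - initial")
    gain <- records$gain
  }
  daily <- if ("daily_intake" %in% names(records)) records$daily_intake
  else records$feed_intake / records$days
  records$sgr <- sgr(records$initial_weight, records$final_weight,
                     records$days)
  records$fcr <- fcr(records$feed_intake, gain)
  records$rfi <- rfi(daily, records$initial_weight, records$final_weight)
  records
}
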