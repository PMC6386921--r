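# Online per-frame cost model. The direct-fusion baseline pipeline runs two
# optical-flow extractions, three convolutional-network passes and up to
# four recurrent passes per frame; the hierarchical pipeline runs one
# convolutional pass and at most one motion LSTM plus one CNN-LSTM pass.
# Component times are measured constants supplied by the user (the
# optical-flow time t_OF enters only the baseline bound).

#' Per-component timing constants (milliseconds per invocation)
#'
#' @param t_of optical-flow extraction time per frame (baseline only).
#' @param t_c1 baseline convolutional-network pass.
#' @param t_l1 baseline recurrent-network pass.
#' @param t_c2 hierarchical pipeline convolutional (CNN) pass.
#' @param t_l2 hierarchical pipeline motion-LSTM pass.
#' @param t_cl hierarchical pipeline CNN-LSTM pass.
#' @return an object of class `cost_params`.
#' @export
#' @examples
#' cost_params(t_of = 12.2, t_c1 = 9.709, t_l1 = 0.659,
#'             t_c2 = 2.395, t_l2 = 0.659, t_cl = 4.103)
cost_params <- function(t_of = 0, t_c1 = 0, t_l1 = 0,
                        t_c2 = 0, t_l2 = 0, t_cl = 0) {
  p <- list(t_of = t_of, t_c1 = t_c1, t_l1 = t_l1,
            t_c2 = t_c2, t_l2 = t_l2, t_cl = t_cl)
  if (any(unlist(p) < 0)) stop_hf("timing constants must be >= 0", class = "hf_invalid")
  structure(p, class = "cost_params")
}

#' Per-frame cost bounds of the direct-fusion baseline
#'
#' Lower bound `2*t_of + 3*t_c1` (flows and CNN passes always run); upper
#' bound adds the four recurrent passes `4*t_l1`.
#'
#' @param p a [cost_params()].
#' @return named numeric `c(lower, upper)` in ms.
#' @export
t1_bounds <- function(p) {
  stopifnot(inherits(p, "cost_params"))
  lower <- 2 * p$t_of + 3 * p$t_c1
  c(lower = lower, upper = lower + 4 * p$t_l1)
}

#' Per-frame cost bounds of the hierarchical pipeline
#'
#' Lower bound `t_c2` (the CNN pass alone, singleton-group route); upper
#' bound `t_l2 + t_cl` (motion LSTM plus CNN-LSTM).
#'
#' @param p a [cost_params()].
#' @return named numeric `c(lower, upper)` in ms.
#' @export
t2_bounds <- function(p) {
  stopifnot(inherits(p, "cost_params"))
  lower <- p$t_c2
  upper <- p$t_l2 + p$t_cl
  if (upper < lower)
    stop_hf("inconsistent timing constants: t_l2 + t_cl < t_c2", class = "hf_invalid")
  c(lower = lower, upper = upper)
}

#' Frame-rate range corresponding to a per-frame time range
#'
#' `fps = 1000 / t` (t in ms): the slowest frame time gives the minimum
#' rate and the fastest the maximum. Raw (unrounded) values are returned;
#' any integer presentation is left to the caller.
#'
#' @param t_lower,t_upper per-frame time bounds in ms, `0 < t_lower <= t_upper`.
#' @return named numeric `c(fps_min, fps_max)`.
#' @export
#' @examples
#' fps_range(53.527, 56.163)
fps_range <- function(t_lower, t_upper) {
  if (t_lower <= 0 || t_upper < t_lower)
    stop_hf("need 0 < t_lower <= t_upper", class = "hf_invalid")
  c(fps_min = 1000 / t_upper, fps_max = 1000 / t_lower)
}
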