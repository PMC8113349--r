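# Task constants ----------------------------------------------------------

#' Standard click-rate stimulus set
#'
#' Six log-spaced click rates between 20 and 125 clicks/s.  Rates below
#' 50 clicks/s belong to the low category (left reward), rates above to
#' the high category (right reward).
#'
#' @return Numeric vector of length 6 (clicks/s).
#' @export
click_rates <- function() {
  exp(seq(log(20), log(125), length.out = 6))
}

#' Normalized log click rate
#'
#' Centers log(click rate) on the midpoint of the log stimulus range and
#' scales it to \[-1, 1\] over the six standard stimuli.
#'
#' @param rate Click rate(s) in clicks/s.
#' @param rate_set Stimulus set defining the normalization (default
#'   [click_rates()]).
#' @return Normalized log rate in \[-1, 1\] for in-range stimuli.
#' @export
log_rate_norm <- function(rate, rate_set = click_rates()) {
  lr <- log(range(rate_set))
  (log(rate) - mean(lr)) / (diff(lr) / 2)
}

#' Four-parameter sigmoid of log click rate
#'
#' `p = y0 + a / (1 + exp(-(x - x0)/b))` where `x = log(click rate)`,
#' `x0` the inflection point, `b` the slope scale, `y0` the lower and
#' `a + y0` the upper bound of P(lick right).
#'
#' @param x Log click rate.
#' @param x0,b,y0,a Sigmoid parameters.
#' @return P(lick right).
#' @export
sigmoid4 <- function(x, x0, b, y0, a) {
  y0 + a / (1 + exp(-(x - x0) / b))
}

default_psychometric <- function() {
  list(x0 = log(50), b = 0.25, y0 = 0.05, a = 0.9)
}

# Behavior generator -------------------------------------------------------

#' Simulate a trial table for the delayed-response licking task
#'
#' Generates per-trial behavior under the standard task structure: six
#' log-spaced click rates (20-125 Hz), uniform delays on
#' `delay_range` (default 0.3-1.5 s), choices drawn from a four-parameter
#' sigmoid of log click rate (with optional manipulation effects added on
#' the logit scale), premature-lick violations with a hazard increasing
#' in delay, and response times decreasing with delay.  RTs are truncated
#' below at 0; trials whose RT would exceed the 3-s response window
#' become misses.
#'
#' @param n_trials Number of trials.
#' @param psycho List `{x0, b, y0, a}` of generating sigmoid parameters.
#' @param delay_range Length-2 numeric, uniform delay support in seconds.
#' @param violation_hazard List `{intercept, delay_coef}` for the logistic
#'   per-trial violation probability `plogis(intercept + delay_coef * delay)`.
#' @param miss_prob Baseline probability that a scored trial is a miss
#'   (no lick within the response window).
#' @param rt_model List `{intercept, delay_slope, noise_sd}` (seconds):
#'   `rt = intercept - delay_slope * delay + N(0, noise_sd)`.  Defaults
#'   reproduce the observed decline of mean RT from roughly 0.57 s at the
#'   shortest delays to 0.45 s at the longest.
#' @param manipulation Optional list describing a perturbation arm:
#'   `list(label = "laser", frac = 0.3, epochs = c("stimulus","delay",
#'   "response","iti"), region = "m2", hemisphere = "left",
#'   bias_shift = <logit shift toward ipsilateral>, slope_factor = <factor
#'   on the logit slope>, per_epoch = <named list overriding bias/slope by
#'   epoch>)`.  Manipulated trials are assigned an epoch uniformly from
#'   `epochs`.
#' @param n_subjects,n_sessions Number of subject and per-subject session
#'   labels to spread trials over.
#' @param response_window Response window in seconds (default 3).
#' @param seed Optional integer seed.
#' @return A `data.frame` trial table with columns `trial_id, subject_id,
#'   session_id, click_rate, log_rate_norm, category, delay, choice,
#'   outcome, rt, manipulation, manip_epoch, manip_region, hemisphere`.
#' @export
sim_behavior <- function(n_trials = 1000,
                         psycho = default_psychometric(),
                         delay_range = c(0.3, 1.5),
                         violation_hazard = list(intercept = -3, delay_coef = 1),
                         miss_prob = 0.02,
                         rt_model = list(intercept = 0.597, delay_slope = 0.099,
                                         noise_sd = 0.1),
                         manipulation = NULL,
                         n_subjects = 1, n_sessions = 1,
                         response_window = 3,
                         seed = NULL) {
  if (n_trials < 1L) stop("n_trials must be >= 1")
  if (any(delay_range <= 0) || diff(delay_range) < 0)
    stop("delay_range must be positive and increasing")
  if (miss_prob < 0 || miss_prob > 1) stop("miss_prob must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  rates <- click_rates()
  rate <- sample(rates, n_trials, replace = TRUE)
  delay <- runif(n_trials, delay_range[1], delay_range[2])
  subject <- sprintf("m%02d", sample.int(n_subjects, n_trials, replace = TRUE))
  session <- paste0(subject, "_s",
                    sample.int(n_sessions, n_trials, replace = TRUE))

  p_right <- sigmoid4(log(rate), psycho$x0, psycho$b, psycho$y0, psycho$a)
  p_right <- pmin(pmax(p_right, 1e-9), 1 - 1e-9)

  manip <- rep("none", n_trials)
  manip_epoch <- rep("none", n_trials)
  manip_region <- rep("none", n_trials)
  hemisphere <- rep("bilateral", n_trials)
  if (!is.null(manipulation)) {
    m <- manipulation
    frac <- if (is.null(m$frac)) 0.3 else m$frac
    if (frac < 0 || frac > 1) stop("manipulation$frac must be in [0, 1]")
    on <- runif(n_trials) < frac
    manip[on] <- if (is.null(m$label)) "laser" else m$label
    epochs <- if (is.null(m$epochs)) c("stimulus", "delay", "response", "iti") else m$epochs
    manip_epoch[on] <- sample(epochs, sum(on), replace = TRUE)
    manip_region[on] <- if (is.null(m$region)) "m2" else m$region
    hemisphere[] <- if (is.null(m$hemisphere)) "left" else m$hemisphere
    # effects on the logit scale; ipsilateral = hemisphere side
    for (i in which(on)) {
      ep <- manip_epoch[i]
      bias <- m$bias_shift %||% 0
      slope <- m$slope_factor %||% 1
      if (!is.null(m$per_epoch) && !is.null(m$per_epoch[[ep]])) {
        bias <- m$per_epoch[[ep]]$bias_shift %||% bias
        slope <- m$per_epoch[[ep]]$slope_factor %||% slope
      }
      lo <- qlogis(p_right[i])
      # bias toward the ipsilateral port: left hemisphere -> more left licks
      sgn <- if (identical(hemisphere[i], "left")) -1 else 1
      p_right[i] <- plogis(lo * slope + sgn * bias)
    }
  }

  choice_right <- runif(n_trials) < p_right
  choice <- ifelse(choice_right, "right", "left")
  category <- ifelse(rate > 50, "high", "low")
  correct <- (category == "high") == choice_right

  p_viol <- plogis(violation_hazard$intercept +
                     violation_hazard$delay_coef * delay)
  if (any(p_viol < 0 | p_viol > 1)) stop("invalid violation probability")
  violated <- runif(n_trials) < p_viol
  missed <- !violated & (runif(n_trials) < miss_prob)

  rt <- rt_model$intercept - rt_model$delay_slope * delay +
    rnorm(n_trials, 0, rt_model$noise_sd)
  rt <- pmax(rt, 0)
  missed <- missed | (!violated & rt > response_window)

  outcome <- ifelse(violated, "violation",
                    ifelse(missed, "miss",
                           ifelse(correct, "correct", "error")))
  choice[violated | missed] <- "none"
  rt[violated | missed] <- NA_real_

  data.frame(
    trial_id = seq_len(n_trials),
    subject_id = subject,
    session_id = session,
    click_rate = rate,
    log_rate_norm = log_rate_norm(rate),
    category = category,
    delay = delay,
    choice = choice,
    outcome = outcome,
    rt = rt,
    manipulation = manip,
    manip_epoch = manip_epoch,
    manip_region = manip_region,
    hemisphere = hemisphere,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Read or write a trial table as CSV
#'
#' Fixed-column CSV round trip for the trial table produced by
#' [sim_behavior()].
#'
#' @param trials Trial table data frame.
#' @param path File path.
#' @return `read_trials()` returns the trial table; `write_trials()`
#'   returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Internal: scored trials (a choice was made and scored)
scored_trials <- function(trials) {
  trials[trials$outcome %in% c("correct", "error"), , drop = FALSE]
}
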