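#' Build a threat-conditioning task schedule
#'
#' Constructs the ordered trial list for the three-phase threat learning task:
#' a pre-conditioning (habituation) phase with 4 presentations per CS, a
#' conditioning phase with 10 presentations per CS in which 8 of the 10 CS+
#' trials co-terminate with the aversive UCS (80% partial reinforcement), and
#' an extinction phase with 8 unreinforced presentations per CS. CS+ and CS-
#' trials are pseudo-randomly interleaved within each phase, with at most two
#' consecutive presentations of the same CS. Two counterbalance orders ("A"
#' and "B") yield different interleavings with identical per-phase counts;
#' the positions of the two unreinforced CS+ conditioning trials are fixed
#' per order (drawn once from trials 2-10, so learning always starts on a
#' reinforced trial).
#'
#' @param order_id Counterbalance order, `"A"` or `"B"`.
#' @param seed Integer seed; the schedule is deterministic given
#'   `(order_id, seed)`.
#' @return A data frame of class `"task_schedule"` with one row per trial in
#'   presentation order and columns `phase` (`"pre"`, `"conditioning"`,
#'   `"extinction"`), `cs` (`"CS+"`, `"CS-"`), `trial` (within-phase, per-CS,
#'   1-based) and `reinforced` (logical). The counterbalance order is stored
#'   in `attr(x, "order_id")`.
#' @examples
#' sch <- build_task_schedule("A", seed = 1)
#' table(sch$phase, sch$cs)
#' sum(sch$reinforced)
#' @export
build_task_schedule <- function(order_id = c("A", "B"), seed = 1L) {
  if (!is.character(order_id) || !all(order_id %in% c("A", "B")) ||
      length(order_id) != 1L) {
    stop("`order_id` must be \"A\" or \"B\"", call. = FALSE)
  }
  seed <- as.integer(seed)
  # distinct, overflow-safe streams for the two counterbalance orders
  derived <- (seed %% 1073741823L) * 2L + (order_id == "B")
  withr::with_seed(derived, {
    phases <- list(pre = 4L, conditioning = 10L, extinction = 8L)
    rows <- lapply(names(phases), function(ph) {
      n <- phases[[ph]]
      cs <- interleave_cs(n, n, max_run = 2L)
      data.frame(
        phase = ph,
        cs = ifelse(cs == 1L, "CS+", "CS-"),
        trial = stats::ave(cs, cs, FUN = seq_along),
        stringsAsFactors = FALSE
      )
    })
    sch <- do.call(rbind, rows)
    unreinforced <- sample(2:10, 2L)
    sch$reinforced <- sch$phase == "conditioning" & sch$cs == "CS+" &
      !(sch$trial %in% unreinforced)
  })
  rownames(sch) <- NULL
  attr(sch, "order_id") <- order_id
  class(sch) <- c("task_schedule", "data.frame")
  sch
}

# Pseudo-random interleaving of two stimulus streams with a cap on
# consecutive same-stimulus presentations. Rejection-samples with a
# feasibility lookahead so balanced phases always succeed.
interleave_cs <- function(n1, n2, max_run = 2L) {
  for (attempt in 1:1000) {
    rem <- c(n1, n2)
    out <- integer(n1 + n2)
    last <- 0L
    run <- 0L
    ok <- TRUE
    for (i in seq_along(out)) {
      choices <- which(rem > 0L)
      if (last %in% choices && run >= max_run) {
        choices <- setdiff(choices, last)
      }
      if (length(choices) == 0L) {
        ok <- FALSE
        break
      }
      pick <- if (length(choices) == 1L) choices else {
        choices[sample.int(length(choices), 1L, prob = rem[choices])]
      }
      out[i] <- pick
      rem[pick] <- rem[pick] - 1L
      run <- if (pick == last) run + 1L else 1L
      last <- pick
    }
    if (ok && !any(rem > 0L)) return(out)
  }
  stop("could not construct an interleaving satisfying the run constraint")
}

#' @export
print.task_schedule <- function(x, ...) {
  cat("Task schedule (order ", attr(x, "order_id"), "): ",
      nrow(x), " trials, ", sum(x$reinforced), " reinforced\n", sep = "")
  NextMethod()
}

# Rows of `schedule` belonging to one phase, in presentation order.
phase_rows <- function(schedule, phase) {
  stopifnot(phase %in% c("pre", "conditioning", "extinction"))
  schedule[schedule$phase == phase, , drop = FALSE]
}
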