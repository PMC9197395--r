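# Pre-conditioning anchor rows with a fixed last-trial value, so fits can
# initialize v(0).
make_pre_rows <- function(schedule, v0, subject_id = "s1") {
  pre <- schedule[schedule$phase == "pre", , drop = FALSE]
  data.frame(subject_id = subject_id, phase = pre$phase, cs = pre$cs,
             trial = pre$trial, scr = v0, ucs_scr = NA_real_, missing = FALSE,
             stringsAsFactors = FALSE)
}

# Wrap observed phase values (aligned to schedule order) into a fittable
# series.
make_series <- function(schedule, phase, scr, ucs_values = NULL, v0 = NULL,
                        subject_id = "s1") {
  ph <- schedule[schedule$phase == phase, , drop = FALSE]
  out <- data.frame(subject_id = subject_id, phase = ph$phase, cs = ph$cs,
                    trial = ph$trial, scr = scr, ucs_scr = NA_real_,
                    missing = is.na(scr), stringsAsFactors = FALSE)
  if (!is.null(ucs_values)) out$ucs_scr[ph$reinforced] <- ucs_values
  if (phase == "conditioning" && !is.null(v0)) {
    out <- rbind(make_pre_rows(schedule, v0, subject_id), out)
  }
  out
}
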