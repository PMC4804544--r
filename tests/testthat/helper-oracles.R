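# Independent mass-balance oracle: integrate central/peripheral drug amounts
# with zero-order input over each infusion window and read off Ac/Vc.
pk_ode_oracle <- function(times, pk, events, rtol = 1e-10, atol = 1e-12) {
  rate_in <- function(t) {
    sum(events$D[t >= events$t_D & t < events$t_D + events$duration] /
        events$duration[t >= events$t_D & t < events$t_D + events$duration])
  }
  rhs <- function(t, y, parms) {
    list(c(rate_in(t) - (pk$k12 + pk$ke) * y[1] + pk$k21 * y[2],
           pk$k12 * y[1] - pk$k21 * y[2],
           y[1] / pk$Vc))  # running AUC of the concentration
  }
  bps <- sort(unique(c(events$t_D, events$t_D + events$duration)))
  t0 <- min(times); t1 <- max(times)
  pieces <- sort(unique(c(t0, bps[bps > t0 & bps < t1], t1)))
  # restart the solver at each dose boundary so the zero-order input is
  # integrated exactly rather than smeared across a step
  y <- c(0, 0, 0)
  out <- NULL
  for (i in seq_len(length(pieces) - 1)) {
    tt <- sort(unique(c(pieces[i], times[times >= pieces[i] & times <= pieces[i + 1]],
                        pieces[i + 1])))
    sol <- deSolve::ode(y, tt, rhs, NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    out <- rbind(out, sol)
    y <- as.numeric(sol[nrow(sol), -1])
  }
  out <- out[!duplicated(out[, 1]), , drop = FALSE]
  list(conc = out[match(times, out[, 1]), 2] / pk$Vc,
       auc = unname(y[3]))
}
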