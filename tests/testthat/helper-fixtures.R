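# shared fixtures: all test data are generated in code

# uniform fine schedule, point samples taken at mid-times
dense_schedule <- function(dt = 0.05, t_end = 67) {
  start <- seq(0, t_end - dt, by = dt)
  frame_schedule(start, start + dt)
}

make_tac <- function(start, end, value, label = "blood", ...) {
  tac(frame_schedule(start, end), value, label = label, ...)
}

# point-sampled TAC: value = f(mid_time)
sampled_tac <- function(schedule, f, label = "blood") {
  tac(schedule, f(schedule$mid), label = label)
}

# a representative noiseless virtual subject's input parameters
default_triexp <- function() {
  triexp_params(55, 4.5, 5, 3.0, 0.15, 0.0121, t_appear = 0.24)
}

# Patlak abscissa values (running normalized time) at the mid-times; zero
# before the appearance time
running_theta <- function(idif, t_appear) {
  vapply(idif$schedule$mid, function(tm) {
    if (tm <= t_appear) 0
    else auc_trapezoid(idif, t_appear, tm, t_appear = t_appear)
  }, numeric(1)) / pmax(idif$value, .Machine$double.xmin)
}
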