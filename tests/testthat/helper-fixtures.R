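# Shared fixtures: small simulated datasets, built once per test run.

angle_between_axes <- function(a, b) {
  acos(min(1, abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
}

rmse_deg <- function(est, truth) sqrt(mean(((est - truth) * 180 / pi)^2))

# standard-protocol hinge dataset (noise-free), cached
std_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_hinge(hinge_rig(), standard_protocol())
    cache
  }
})

# a short, cheap dataset for structural tests
short_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_hinge(
        hinge_rig(rate = 50),
        motion_profile(type = "sinusoid", amplitude_deg = 20, freq_hz = 0.5,
                       duration = 6, still_lead = 1.5, still_tail = 1.5,
                       smooth = 0.5,
                       base_rotation = list(
                         list(axis = c(0, 0, 1), amplitude_deg = 15,
                              freq_hz = 0.4),
                         list(axis = c(0, 1, 0), amplitude_deg = 10,
                              freq_hz = 0.31))))
    }
    cache
  }
})

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
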