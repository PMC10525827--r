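# Small in-code fixtures shared across test files.

# A tiny hand-built track: two labels, explicit coordinates.
make_toy_track <- function(n = 6, labels = c("UpperBeakTip", "LowerBeakTip"),
                           frame_rate = 50) {
  x <- matrix(seq_len(n * length(labels)), n, length(labels),
              dimnames = list(NULL, labels))
  y <- x + 100
  lik <- matrix(0.9, n, length(labels), dimnames = list(NULL, labels))
  pose_track("toy", x, y, lik, frame_rate = frame_rate)
}

# Track whose beak landmarks follow prescribed gap values exactly.
make_gap_track <- function(gap, fulcrum = c(-12, 5), frame_rate = 50,
                           trial_id = "gap") {
  n <- length(gap)
  labels <- c("beak_upper", "beak_lower", "beak_fulcrum")
  x <- cbind(beak_upper = rep(100, n), beak_lower = rep(100, n),
             beak_fulcrum = rep(100 + fulcrum[1], n))
  y <- cbind(beak_upper = rep(100, n), beak_lower = 100 + gap,
             beak_fulcrum = rep(100 + fulcrum[2], n))
  lik <- matrix(1, n, 3, dimnames = list(NULL, labels))
  pose_track(trial_id, x, y, lik, frame_rate = frame_rate)
}

toy_scheme <- function() {
  bodypart_scheme(beak_upper = "beak_upper", beak_lower = "beak_lower",
                  beak_fulcrum = "beak_fulcrum")
}

# A design whose windows fit inside `n_frames` at 50 fps with a
# 120 s baseline; Pinch first.
make_toy_design <- function(embryo_id = "e01", embryonic_day = 16,
                            frame_rate = 50) {
  B <- 120 * frame_rate
  trial_design(embryo_id, embryonic_day,
               data.frame(kind = c("Pinch", "Touch"),
                          onset_frame = c(B, B + 50 + 150 * frame_rate + B),
                          release_frame = c(B + 50, B + 100 + 150 * frame_rate + B)),
               baseline_duration = 120)
}

# Interval-sum table for the stats module: n embryos, Pinch/Touch cells
# BL + four post intervals, embryo offsets, optional Pinch effect at
# given intervals.
make_interval_table <- function(n_embryos = 16, noise_sd = 1, embryo_sd = 2,
                                effect = 0, effect_intervals = "0-30",
                                base = 100, seed = 1) {
  set.seed(seed)
  ivs <- c("BL", "0-30", "30-60", "60-90", "90-120")
  g <- expand.grid(embryo_id = sprintf("e%02d", seq_len(n_embryos)),
                   stimulus = c("Pinch", "Touch"), interval = ivs,
                   stringsAsFactors = FALSE)
  off <- stats::rnorm(n_embryos, 0, embryo_sd)
  names(off) <- sprintf("e%02d", seq_len(n_embryos))
  g$sum <- base + off[g$embryo_id] + stats::rnorm(nrow(g), 0, noise_sd) +
    ifelse(g$stimulus == "Pinch" & g$interval %in% effect_intervals, effect, 0)
  g
}
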