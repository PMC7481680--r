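# Shared test fixtures: tiny hand-built streams and short generator configs.

make_stream <- function(t = seq(0, 10, by = 0.1),
                        participant = "p1", sensor = "k1",
                        head = NULL, valid = NULL) {
  n <- length(t)
  if (is.null(head)) head <- cbind(sin(t), 1.2 + 0 * t, cos(t))
  joints <- list(head = head,
                 neck = head + matrix(c(0, -0.12, 0), n, 3, byrow = TRUE),
                 shoulder_left = head + matrix(c(-0.2, -0.25, 0), n, 3,
                                               byrow = TRUE),
                 shoulder_right = head + matrix(c(0.2, -0.25, 0), n, 3,
                                                byrow = TRUE),
                 spine_shoulder = head + matrix(c(0, -0.25, 0.06), n, 3,
                                                byrow = TRUE))
  orient <- cbind(10 * sin(t / 3), 5 * cos(t / 2), 0 * t)
  skeleton_stream(participant, sensor, t, joints, orient, valid)
}

short_schedule <- function() {
  data.frame(condition = c("conversation", "pause", "cooperative",
                           "competitive"),
             duration_s = c(60, 20, 60, 60))
}

small_dyad <- function(seed = 1, ...) {
  generate_dyad(dyad_config(schedule = short_schedule(), seed = seed, ...))
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr_r <- qr(m)
  q <- qr.Q(qr_r)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
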