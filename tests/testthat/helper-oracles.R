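# Independent brute-force oracles and fixture builders. These re-derive the
# behavioural metrics sample by sample with plain loops so the vectorized
# implementations can be checked against them.

# Zone of a single (x, z) point: slow scalar re-derivation.
oracle_zone <- function(x, z, thr) {
  ax <- abs(x)
  az <- abs(z)
  if (az > thr && ax > thr) {
    if (az >= ax) "open" else "closed"
  } else if (az > thr) {
    "open"
  } else if (ax > thr) {
    "closed"
  } else {
    "center"
  }
}

oracle_metrics <- function(traj, geom) {
  s <- traj$samples
  s <- s[s$t >= 0 & s$t < traj$session$task_duration, ]
  dt <- 1 / traj$sample_rate
  n <- nrow(s)
  zones <- character(n)
  for (i in seq_len(n)) {
    zones[i] <- oracle_zone(s$x[i], s$z[i], geom$zone_threshold)
  }
  time_open <- time_closed <- time_center <- 0
  for (i in seq_len(n)) {
    if (zones[i] == "open") time_open <- time_open + dt
    else if (zones[i] == "closed") time_closed <- time_closed + dt
    else time_center <- time_center + dt
  }
  entries_open <- entries_closed <- 0L
  for (i in 2:n) {
    if (zones[i] == "open" && zones[i - 1] != "open") {
      entries_open <- entries_open + 1L
    }
    if (zones[i] == "closed" && zones[i - 1] != "closed") {
      entries_closed <- entries_closed + 1L
    }
  }
  lat_first <- traj$session$task_duration
  for (i in seq_len(n)) {
    if (zones[i] == "open") { lat_first <- s$t[i]; break }
  }
  lat_end <- traj$session$task_duration
  for (i in seq_len(n)) {
    if (abs(s$z[i]) >= geom$end_threshold) { lat_end <- s$t[i]; break }
  }
  dist <- 0
  for (i in 2:n) {
    dist <- dist + sqrt((s$x[i] - s$x[i - 1])^2 + (s$z[i] - s$z[i - 1])^2)
  }
  vel <- function(kind) {
    acc <- c()
    for (i in 2:n) {
      if (zones[i] == kind && zones[i - 1] == kind) {
        step <- sqrt((s$x[i] - s$x[i - 1])^2 + (s$z[i] - s$z[i - 1])^2)
        acc <- c(acc, step / dt)
      }
    }
    if (length(acc)) mean(acc) else NA_real_
  }
  list(time_open = time_open, time_closed = time_closed,
       time_center = time_center, entries_open = entries_open,
       entries_closed = entries_closed, latency_first_open = lat_first,
       latency_end_exploration = lat_end, total_distance = dist / 100,
       mean_velocity_open = vel("open"), mean_velocity_closed = vel("closed"))
}

# A 5 Hz trajectory from explicit planar coordinates.
make_traj <- function(x, z, rate = 5, task_duration = NULL, y = 165,
                      id = "fix") {
  n <- length(x)
  if (is.null(task_duration)) task_duration <- n / rate
  samples <- data.frame(t = (seq_len(n) - 1) / rate, x = x, y = y, z = z,
                        rx = 0, ry = 0, rz = 0)
  trajectory(samples, session_meta(id, task_duration = task_duration),
             sample_rate = rate)
}

# Random 5 Hz trajectory: a planar random walk over the maze bounding box,
# free to leave the plus shape (tracking noise does), plus occasional jumps
# across zones so all transition types occur.
random_traj <- function(n = 1500, rate = 5, scale = 40) {
  x <- cumsum(stats::rnorm(n, 0, scale)) %% 360 - 180
  z <- cumsum(stats::rnorm(n, 0, scale)) %% 360 - 180
  make_traj(x, z, rate = rate)
}

# Random rigid rotation with determinant +1.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
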