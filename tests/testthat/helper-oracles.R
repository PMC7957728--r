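# Independent oracles used across the suite. Each reimplements the checked
# quantity from first principles, sharing no code path with the package.

# --- kinetics: adaptive ODE integration of the two-compartment system ----
# dCf/dt = K1 Cp - (k2 + k3) Cf + k4 Cb ; dCb/dt = k3 Cf - k4 Cb
ode_2tc_oracle <- function(params, cp_fun, times, rtol = 1e-10) {
  deriv <- function(t, y, parms) {
    cpv <- cp_fun(t)
    list(c(params$K1 * cpv - (params$k2 + params$k3) * y[1] +
             params$k4 * y[2],
           params$k3 * y[1] - params$k4 * y[2]))
  }
  sol <- deSolve::ode(c(0, 0), c(0, times), deriv, NULL,
                      rtol = rtol, atol = rtol)
  tissue <- sol[-1, 2] + sol[-1, 3]
  (1 - params$VB) * tissue + params$VB * cp_fun(times)
}

# --- fractal: exhaustive box-segment intersection enumeration -----------
# Counts cells (i, j) of the 2^k x 2^k dyadic grid whose half-open region
# [i*eps, (i+1)*eps) x [j*eps, (j+1)*eps) (closed at the square's top/right
# edges) intersects the polyline. Liang-Barsky clipping per segment.
brute_force_box_count <- function(x, y, k) {
  nb <- 2L^k
  eps <- 1 / nb
  clip <- function(x0, y0, x1, y1, lo_x, hi_x, lo_y, hi_y) {
    # returns clipped [t0, t1] of the segment inside the closed box, or NULL
    dx <- x1 - x0; dy <- y1 - y0
    t0 <- 0; t1 <- 1
    for (spec in list(c(-dx, x0 - lo_x), c(dx, hi_x - x0),
                      c(-dy, y0 - lo_y), c(dy, hi_y - y0))) {
      p <- spec[1]; q <- spec[2]
      if (p == 0) { if (q < 0) return(NULL) } else {
        r <- q / p
        if (p < 0) { if (r > t1) return(NULL); if (r > t0) t0 <- r }
        else { if (r < t0) return(NULL); if (r < t1) t1 <- r }
      }
    }
    c(t0, t1)
  }
  occupied <- 0L
  for (i in seq_len(nb) - 1L) {
    for (j in seq_len(nb) - 1L) {
      lo_x <- i * eps; hi_x <- (i + 1) * eps
      lo_y <- j * eps; hi_y <- (j + 1) * eps
      hit <- FALSE
      for (s in seq_len(length(x) - 1L)) {
        tt <- clip(x[s], y[s], x[s + 1], y[s + 1], lo_x, hi_x, lo_y, hi_y)
        if (is.null(tt)) next
        # half-open membership: the clipped piece must contain a point with
        # x < hi_x (unless i is the last column) and y < hi_y (unless j is
        # the last row); a degenerate touch on the shared upper edge
        # belongs to the neighbouring cell.
        cx <- x[s] + tt * (x[s + 1] - x[s])
        cy <- y[s] + tt * (y[s + 1] - y[s])
        ok_x <- (i == nb - 1L) || any(cx < hi_x)
        ok_y <- (j == nb - 1L) || any(cy < hi_y)
        # positive-length overlap required: a zero-length corner touch
        # belongs to no cell (it separates two sub-segments that each
        # carry their own cells)
        if (ok_x && ok_y && tt[2] > tt[1]) { hit <- TRUE; break }
      }
      if (hit) occupied <- occupied + 1L
    }
  }
  occupied
}

fd_from_counts <- function(counts, levels) {
  stats::cov(log(2^levels), log(counts)) / stats::var(log(2^levels))
}

# --- survival: hand product-limit and log-rank computations -------------
hand_km <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- as.logical(events[ord])
  ut <- sort(unique(times[events]))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (r in seq_along(ut)) {
    at_risk <- sum(times >= ut[r])
    d <- sum(events & times == ut[r])
    s <- s * (1 - d / at_risk)
    out$surv[r] <- s
  }
  out$median <- NA_real_
  med <- out$time[out$surv <= 0.5 + 1e-12]
  list(curve = out[, c("time", "surv")],
       median = if (length(med)) min(med) else NA_real_)
}

# Unweighted two-group log-rank: hypergeometric sums over event times.
hand_logrank <- function(time, event, group) {
  group <- as.integer(factor(group))  # 1 / 2
  ut <- sort(unique(time[event > 0]))
  o_minus_e <- 0; v <- 0; obs <- c(0, 0); expd <- c(0, 0)
  for (t in ut) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == 1L)
    d <- sum(event > 0 & time == t)
    d1 <- sum(event > 0 & time == t & group == 1L)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    obs <- obs + c(d1, d - d1)
    expd <- expd + c(e1, d - e1)
  }
  stat <- o_minus_e^2 / v
  list(statistic = stat,
       p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
       observed = obs, expected = expd)
}

# Permutation p-value of the log-rank statistic under label exchange.
permutation_logrank_p <- function(time, event, group, n_perm, seed) {
  obs <- hand_logrank(time, event, group)$statistic
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    g <- sample(group)
    s <- hand_logrank(time, event, g)$statistic
    if (s >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

# Default fixtures shared across files
proto24 <- dynpet::default_protocol()
feng_cp <- dynpet::feng_input_function()
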