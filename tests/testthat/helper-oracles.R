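# Exhaustive-enumeration oracles, independent of the package's DP recurrences.

# All feasible single-line paths across `cost` (rows = candidates, cols =
# sequential positions); returns the minimal total cost.
brute_dp <- function(cost, delta_max = 3, gamma = 20, closed = FALSE) {
  H <- nrow(cost); W <- ncol(cost)
  ends <- seq_len(H)
  starts <- ends
  costs <- cost[, 1]
  if (W > 1) for (w in 2:W) {
    idx <- rep(seq_along(ends), each = H)
    nxt <- rep(seq_len(H), times = length(ends))
    keep <- abs(nxt - ends[idx]) <= delta_max
    idx <- idx[keep]; nxt <- nxt[keep]
    costs <- costs[idx] + cost[cbind(nxt, w)] *
      (1 + abs(nxt - ends[idx]) / gamma)
    starts <- starts[idx]
    ends <- nxt
  }
  if (closed) {
    keep <- abs(starts - ends) <= delta_max
    costs <- costs[keep]
  }
  if (!length(costs)) return(Inf)
  min(costs)
}

# All feasible dual-line state sequences; node cost = cost_outer(y1) +
# cost_inner(y2); returns the minimal total cost.
brute_mdp <- function(cost_outer, cost_inner, delta1 = 1, delta2 = 1,
                      alpha1 = 0.2, alpha2 = 0.2, alpha3 = 0.2,
                      dmin_px = 2, dmax_px = 6) {
  H <- nrow(cost_outer); W <- ncol(cost_outer)
  st <- expand.grid(y1 = seq_len(H), d = dmin_px:dmax_px)
  st <- st[st$y1 + st$d <= H, ]
  y1 <- st$y1; y2 <- st$y1 + st$d
  costs <- cost_outer[cbind(y1, 1)] + cost_inner[cbind(y2, 1)]
  if (W > 1) for (x in 2:W) {
    moves <- expand.grid(d1 = -delta1:delta1, d2 = -delta2:delta2)
    n <- length(y1); m <- nrow(moves)
    idx <- rep(seq_len(n), times = m)
    d1 <- rep(moves$d1, each = n); d2 <- rep(moves$d2, each = n)
    ny1 <- y1[idx] + d1; ny2 <- y2[idx] + d2
    sep <- ny2 - ny1
    keep <- ny1 >= 1 & ny2 <= H & sep >= dmin_px & sep <= dmax_px
    idx <- idx[keep]; d1 <- d1[keep]; d2 <- d2[keep]
    ny1 <- ny1[keep]; ny2 <- ny2[keep]
    dd <- (ny2 - ny1) - (y2[idx] - y1[idx])
    node <- cost_outer[cbind(ny1, x)] + cost_inner[cbind(ny2, x)]
    costs <- costs[idx] + node * (1 + alpha1)^abs(d1) * (1 + alpha2)^abs(d2) *
      (1 + alpha3 * abs(dd))
    y1 <- ny1; y2 <- ny2
  }
  if (!length(costs)) return(Inf)
  min(costs)
}
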