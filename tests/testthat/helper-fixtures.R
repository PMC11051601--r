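# Shared fixtures and independent oracles used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small optical geometries keep FFT-based tests fast.
tiny_optics <- function(n = 64, chamber_depth = 280) {
  optical_config(frame_width = n, frame_height = n,
                 chamber_depth = chamber_depth)
}

# A band-limited random complex field: white noise with its evanescent
# components removed (one zero-distance pass through the kernel).
band_limited_field <- function(optics, seed = 1) {
  set.seed(seed)
  n <- optics$frame_width
  raw <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n)
  propagate(raw, 0, optics)
}

# Single-scatterer frame at a given position.
one_scatterer_frame <- function(optics, x_um, y_um, z_um, amplitude = 0.15,
                                noise_sd = 0) {
  render_hologram(
    tibble::tibble(x_um = x_um, y_um = y_um, z_um = z_um,
                   amplitude = amplitude),
    optics, noise_sd = noise_sd)
}

# ---- independent oracles -------------------------------------------------

# Greedy NMS by literal enumeration of the rule.
oracle_nms <- function(det, iou_thr) {
  det <- det[order(-det$confidence), ]
  kept <- det[0, ]
  for (i in seq_len(nrow(det))) {
    ok <- TRUE
    for (j in seq_len(nrow(kept))) {
      if (box_iou(unlist(det[i, c("x_center", "y_center", "width", "height")]),
                  unlist(kept[j, c("x_center", "y_center", "width", "height")])) >
          iou_thr) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- rbind(kept, det[i, ])
  }
  kept
}

# Greedy confidence-ordered matching by literal enumeration.
oracle_match <- function(det, gt, iou_thr) {
  det <- det[order(-det$confidence), ]
  taken <- rep(FALSE, nrow(gt))
  tp <- rep(FALSE, nrow(det))
  for (i in seq_len(nrow(det))) {
    best <- 0; best_iou <- -1
    for (j in seq_len(nrow(gt))) {
      if (taken[j]) next
      v <- box_iou(unlist(det[i, c("x_center", "y_center", "width", "height")]),
                   unlist(gt[j, c("x_center", "y_center", "width", "height")]))
      if (v > best_iou) { best_iou <- v; best <- j }
    }
    if (best > 0 && best_iou >= iou_thr) { tp[i] <- TRUE; taken[best] <- TRUE }
  }
  tp
}

# 101-point interpolated AP from first principles: evaluate precision and
# recall at every distinct confidence cutoff, then average interpolated
# precision over the recall grid.
oracle_ap <- function(conf, tp, n_gt) {
  cuts <- sort(unique(conf), decreasing = TRUE)
  pr <- t(vapply(cuts, function(ct) {
    sel <- conf >= ct
    c(p = sum(tp[sel]) / sum(sel), r = sum(tp[sel]) / n_gt)
  }, numeric(2)))
  mean(vapply((0:100) / 100, function(r) {
    ok <- pr[, "r"] >= r - 1e-12
    if (any(ok)) max(pr[ok, "p"]) else 0
  }, numeric(1)))
}

# Minimum-total-distance bipartite assignment by exhaustive permutation
# (rows to columns, n_row <= 5). Returns the column index for each row
# (NA = unassigned when costs are forbidden).
oracle_assign <- function(cost, max_cost = Inf) {
  nr <- nrow(cost); nc <- ncol(cost)
  big <- 1e9
  c2 <- cost
  c2[c2 > max_cost] <- big
  if (nr <= nc) {
    perms <- combinat_perms(nc, nr)
    best <- NULL; best_val <- Inf
    for (p in perms) {
      v <- sum(c2[cbind(seq_len(nr), p)])
      if (v < best_val) { best_val <- v; best <- p }
    }
    out <- best
    out[c2[cbind(seq_len(nr), best)] >= big / 2] <- NA
    out
  } else {
    stop("oracle_assign expects nrow <= ncol")
  }
}

# All ordered selections of k items from n (small n only).
combinat_perms <- function(n, k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == k) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (x in remaining) rec(c(prefix, x), setdiff(remaining, x))
  }
  rec(integer(0), seq_len(n))
  out
}

# Radial |I - 1| profile of a centred pattern; returns the envelope by
# integer radius bin.
radial_profile <- function(frame, cx_px, cy_px) {
  ny <- nrow(frame); nx <- ncol(frame)
  r <- sqrt(outer((seq_len(ny) - 1 - cy_px)^2, (seq_len(nx) - 1 - cx_px)^2, `+`))
  rb <- floor(r)
  env <- tapply(abs(frame - 1), rb, max)
  tibble::tibble(radius_px = as.numeric(names(env)), envelope = as.numeric(env))
}

# Locations (px) of local minima of a profile vector.
profile_minima <- function(v) {
  which(diff(sign(diff(v))) > 0) + 1
}
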