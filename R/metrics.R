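#' Identify the huddle by single-linkage clustering
#'
#' Birds are clustered by single linkage at `link_distance` (default 1 m,
#' twice the body diameter); the largest cluster is "the huddle". Ties on
#' cluster size are broken toward the cluster with the lower centroid x and
#' flagged. The huddle centre is the member centroid, the radius the 90th
#' percentile of member distances to the centre (robust to stragglers), and
#' the area the circle `pi * radius^2`. A colony whose largest cluster holds
#' fewer than half the birds is flagged dispersed.
#'
#' @param x,y colony positions (m).
#' @param link_distance single-linkage cut distance (m).
#' @return List with `members` (indices), `center`, `radius`, `area`,
#'   `n_members`, `dispersed`, `tie`.
#' @export
huddle_membership <- function(x, y, link_distance = 1.0) {
  n <- length(x)
  if (n == 0L) stop("colony must be non-empty")
  if (n == 1L) {
    cl <- rep(1L, 1)
  } else {
    hc <- hclust(dist(cbind(x, y)), method = "single")
    cl <- cutree(hc, h = link_distance)
  }
  sizes <- tabulate(cl)
  biggest <- which(sizes == max(sizes))
  tie <- length(biggest) > 1L
  if (tie) {
    cent_x <- vapply(biggest, function(k) mean(x[cl == k]), numeric(1))
    biggest <- biggest[which.min(cent_x)]
  } else {
    biggest <- biggest[1]
  }
  members <- which(cl == biggest)
  center <- c(mean(x[members]), mean(y[members]))
  d <- sqrt((x[members] - center[1])^2 + (y[members] - center[2])^2)
  radius <- if (length(members) > 1L) unname(quantile(d, 0.9)) else 0
  list(members = members, center = center, radius = radius,
       area = pi * radius^2, n_members = length(members),
       dispersed = length(members) < n / 2, tie = tie)
}

#' Classify huddle members into windward/leeward/side/interior sectors
#'
#' Members closer to the centre than `edge_fraction * radius` are interior;
#' the rest are classified by the angle between their offset from the centre
#' and the upwind direction: within +/-45 degrees upwind is windward, within
#' +/-45 degrees downwind is leeward, otherwise side. With zero wind all
#' perimeter members are side.
#'
#' @param x,y colony positions.
#' @param huddle result of [huddle_membership()].
#' @param wind_direction unit 2-vector of the direction the wind blows
#'   toward (physical frame).
#' @param edge_fraction interior cut as a fraction of the huddle radius.
#' @return Character vector over the whole colony: sector labels for
#'   members, `"unassigned"` for non-members.
#' @export
classify_sectors <- function(x, y, huddle, wind_direction = c(0, 1),
                             edge_fraction = 0.75) {
  out <- rep("unassigned", length(x))
  m <- huddle$members
  dxv <- x[m] - huddle$center[1]
  dyv <- y[m] - huddle$center[2]
  d <- sqrt(dxv^2 + dyv^2)
  lab <- rep("side", length(m))
  interior <- d < edge_fraction * huddle$radius
  lab[interior] <- "interior"
  wnorm <- sqrt(sum(wind_direction^2))
  if (wnorm > 0) {
    wd <- wind_direction / wnorm
    upwind <- -wd
    cosang <- ifelse(d > 0, (dxv * upwind[1] + dyv * upwind[2]) / d, 0)
    lab[!interior & cosang >= cos(pi / 4)] <- "windward"
    lab[!interior & -cosang >= cos(pi / 4)] <- "leeward"
  }
  out[m] <- lab
  out
}

#' Table-style snapshot summary
#'
#' Sample mean, SD (n-1 denominator), minimum and maximum of the per-bird
#' temperature; percent of birds whose wind-chill temperature lies in the
#' TNZ (both bounds inclusive); and the huddle density (members over the
#' fitted circular area when a huddle exists, colony count over domain area
#' when dispersed).
#'
#' @param colony data frame with at least `x`, `y`, `Texp`, `Twc`.
#' @param domain `c(Lx, Ly)` extent (m).
#' @param params a [thermo_params()].
#' @param link_distance single-linkage cut distance (m).
#' @param temperature which per-bird temperature the statistics summarise:
#'   `"Twc"` (wind-chill corrected; default, the temperature that drives
#'   behaviour) or `"Texp"`.
#' @param time_min snapshot time stamp (minutes), echoed into the row.
#' @return One-row data frame (a huddle-summary row).
#' @export
summarize_huddle <- function(colony, domain = c(50, 100),
                             params = thermo_params(), link_distance = 1.0,
                             temperature = c("Twc", "Texp"), time_min = NA) {
  temperature <- match.arg(temperature)
  n <- nrow(colony)
  if (is.null(n) || n == 0L) stop("colony must be non-empty")
  tv <- colony[[temperature]]
  h <- huddle_membership(colony$x, colony$y, link_distance)
  density <- if (!h$dispersed && h$area > 0) h$n_members / h$area
             else n / (domain[1] * domain[2])
  pct <- 100 * mean(colony$Twc >= params$LCT & colony$Twc <= params$UCT)
  data.frame(
    time_min = time_min,
    mean_T = mean(tv),
    sd_T = if (n > 1L) sd(tv) else 0,
    min_T = min(tv), max_T = max(tv),
    pct_in_TNZ = pct,
    huddle_density = density,
    huddle_radius = h$radius,
    n_members = h$n_members,
    dispersed = h$dispersed,
    sd_flag = n == 1L
  )
}

#' Radial profiles of temperature and density within the huddle
#'
#' Bins members by normalised distance to the huddle centre (`r / radius`,
#' over [0, 1.5]) and reports the per-bin mean exposed temperature and areal
#' density (count over annulus area). Empty bins are reported as `NA`, not
#' zero.
#'
#' @param colony data frame with `x`, `y` and the temperature column.
#' @param huddle result of [huddle_membership()].
#' @param n_bins number of radial bins.
#' @param temperature column to profile (default `"Texp"`).
#' @param r_max outer edge in huddle radii.
#' @return Data frame with `r_mid` (normalised bin midpoint), `r_mean`
#'   (mean normalised member radius in the bin, `NA` when empty), `mean_T`,
#'   `density` (birds/m^2), `count`.
#' @export
radial_profiles <- function(colony, huddle, n_bins = 8,
                            temperature = "Texp", r_max = 1.5) {
  m <- huddle$members
  if (length(m) < n_bins)
    stop("fewer huddle members than bins; use a smaller n_bins")
  if (huddle$radius <= 0) stop("degenerate huddle radius")
  r <- sqrt((colony$x[m] - huddle$center[1])^2 +
            (colony$y[m] - huddle$center[2])^2) / huddle$radius
  breaks <- seq(0, r_max, length.out = n_bins + 1)
  bin <- cut(r, breaks, include.lowest = TRUE)
  tv <- colony[[temperature]][m]
  counts <- as.integer(table(bin))
  mean_T <- as.numeric(tapply(tv, bin, mean))
  r_mean <- as.numeric(tapply(r, bin, mean))
  # annulus areas in physical units
  ann <- pi * huddle$radius^2 * diff(breaks^2)
  density <- counts / ann
  density[counts == 0L] <- NA_real_
  data.frame(r_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
             r_mean = r_mean, mean_T = mean_T, density = density,
             count = counts)
}
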