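# Config parsing, colony readers/writers, and seeded fixture generation.
# CSV dialect: comma-separated, '.' decimal, UTF-8, '#'-prefixed comment
# lines permitted before the header.

# run `expr` under a temporary seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# named substreams off one master seed, so adding a consumer never perturbs
# existing streams
substream_seed <- function(master, name) {
  offsets <- c(placement = 11L, fixture = 23L, scatter = 37L)
  off <- offsets[[name]]
  if (is.null(off)) stop("unknown random substream: ", name)
  (as.integer(master) * 1009L + off) %% 2147483647L
}

#' Generate a seeded fixture colony
#'
#' Deterministic layouts for tests and initialisation: `"random"` uniform
#' placement with a minimum separation (rejection sampling), `"disc"` a
#' packed sunflower-spiral disc, `"two_clusters"` two separated discs.
#'
#' @param n number of birds.
#' @param domain `c(Lx, Ly)` extent (m).
#' @param seed integer seed.
#' @param pattern layout pattern.
#' @param min_separation minimum pairwise distance for `"random"` (m).
#' @param disc_radius disc radius for `"disc"`/`"two_clusters"` (m).
#' @param center disc centre (defaults to the domain centre).
#' @param cluster_gap centre-to-centre distance for `"two_clusters"` (m).
#' @return Data frame with `id`, `x`, `y`.
#' @export
make_fixture_colony <- function(n, domain = c(50, 100), seed = 1,
                                pattern = c("random", "disc", "two_clusters"),
                                min_separation = 0.5, disc_radius = 5,
                                center = NULL, cluster_gap = 30) {
  pattern <- match.arg(pattern)
  if (n < 1) stop("need at least one bird")
  if (is.null(center)) center <- domain / 2
  sunflower <- function(k, radius, at) {
    ang <- (seq_len(k) - 0.5) * pi * (3 - sqrt(5))
    r <- radius * sqrt((seq_len(k) - 0.5) / k)
    cbind(at[1] + r * cos(ang), at[2] + r * sin(ang))
  }
  pts <- switch(pattern,
    random = with_seed(substream_seed(seed, "fixture"), {
      margin <- min_separation / 2
      xs <- numeric(n); ys <- numeric(n)
      placed <- 0L; tries <- 0L
      while (placed < n) {
        if (tries > 200L * n)
          stop("cannot place ", n, " birds at separation ", min_separation,
               " in this domain")
        px <- runif(1, margin, domain[1] - margin)
        py <- runif(1, margin, domain[2] - margin)
        ok <- placed == 0L ||
          min((xs[1:placed] - px)^2 + (ys[1:placed] - py)^2) >=
            min_separation^2
        if (ok) { placed <- placed + 1L; xs[placed] <- px; ys[placed] <- py }
        tries <- tries + 1L
      }
      cbind(xs, ys)
    }),
    disc = sunflower(n, disc_radius, center),
    two_clusters = {
      n1 <- ceiling(n / 2); n2 <- n - n1
      off <- c(cluster_gap / 2, 0)
      rbind(sunflower(n1, disc_radius, center - off),
            if (n2 > 0) sunflower(n2, disc_radius, center + off))
    })
  out <- data.frame(id = seq_len(n), x = pts[, 1], y = pts[, 2])
  bad <- out$x < 0 | out$x > domain[1] | out$y < 0 | out$y > domain[2]
  if (any(bad)) stop("fixture layout does not fit the domain")
  out
}

#' Write a colony (or snapshot) file
#'
#' @param colony data frame with at least `id`, `x`, `y`.
#' @param path output file.
#' @param comment optional '#' comment lines written before the header.
#' @export
write_colony <- function(colony, path, comment = NULL) {
  stopifnot(all(c("id", "x", "y") %in% names(colony)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.csv(colony, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a colony file
#'
#' Expects a header with at least `id`, `x`, `y`; `#` comment lines before
#' the header are skipped. Ids must be unique and, when a domain is given,
#' coordinates must lie inside it.
#'
#' @param path input file.
#' @param domain optional `c(Lx, Ly)` used to validate coordinates.
#' @return Data frame.
#' @export
read_colony <- function(path, domain = NULL) {
  if (!file.exists(path)) stop("colony file not found: ", path)
  df <- read.csv(path, comment.char = "#")
  need <- c("id", "x", "y")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("colony file is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$id)) stop("colony ids must be unique")
  if (!is.null(domain) &&
      any(df$x < 0 | df$x > domain[1] | df$y < 0 | df$y > domain[2]))
    stop("colony coordinates fall outside the declared domain")
  df
}

#' Load a simulation configuration from YAML or JSON
#'
#' Keys are grouped as in [sim_config()]: top-level scalars
#' (`n_penguins`, `ambient_temperature`, `total_time`, `coupling_interval`,
#' `seed`, ...) plus optional `grid`, `wind`, `thermo`, `behavior`, `eos`
#' sections whose entries override the corresponding constructor defaults.
#' Unknown keys are an error, not a warning; an empty file yields the
#' all-defaults configuration. The fully resolved configuration is what the
#' driver echoes into its run log, so a run is reproducible from its log
#' alone.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("unsupported config format: .", ext,
                   " (YAML or JSON expected)")
  if (is.null(raw)) raw <- list()
  config_from_list(raw)
}

# build a sim_config from a nested list, rejecting unknown keys
config_from_list <- function(raw) {
  groups <- c("grid", "wind", "thermo", "behavior", "eos")
  top_ok <- c(names(formals(sim_config)), groups, "huddlesim_version")
  top_ok <- setdiff(top_ok, c("grid", "wind", "thermo", "behavior"))
  raw$huddlesim_version <- NULL
  unknown <- setdiff(names(raw), c(top_ok, groups))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  build <- function(ctor, section) {
    args <- raw[[section]]
    if (is.null(args)) return(ctor())
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad))
      stop("unknown config keys in `", section, "`: ",
           paste(paste0(section, ".", bad), collapse = ", "))
    do.call(ctor, args)
  }
  eos <- build(eos_params, "eos")
  beh_args <- raw[["behavior"]]
  if (is.null(beh_args)) beh_args <- list()
  bad <- setdiff(names(beh_args), names(formals(behavior_params)))
  if (length(bad))
    stop("unknown config keys in `behavior`: ",
         paste(paste0("behavior.", bad), collapse = ", "))
  beh_args$eos <- eos
  top <- raw[setdiff(names(raw), groups)]
  args <- c(top, list(grid = build(grid_spec, "grid"),
                      wind = build(wind_config, "wind"),
                      thermo = build(thermo_params, "thermo"),
                      behavior = do.call(behavior_params, beh_args)))
  do.call(sim_config, args)
}

#' Serialise a configuration to a plain list
#'
#' Inverse of the grouping used by [load_config()]; round-trips through
#' YAML/JSON to an identical configuration.
#'
#' @param config a [sim_config()].
#' @return Nested list.
#' @export
config_to_list <- function(config) {
  strip <- function(z, drop = character(0)) {
    z <- unclass(z)
    z[setdiff(names(z), drop)]
  }
  list(
    n_penguins = config$n_penguins,
    ambient_temperature = config$ambient_temperature,
    total_time = config$total_time,
    coupling_interval = config$coupling_interval,
    snapshot_times = config$snapshot_times,
    seed = config$seed,
    output_dir = config$output_dir,
    grid = strip(config$grid)[c("Lx", "Ly", "dx")],
    wind = strip(config$wind),
    thermo = strip(config$thermo),
    behavior = strip(config$behavior,
                     drop = c("eos", "kernel", "repulsion_kernel")),
    eos = strip(config$behavior$eos)
  )
}
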