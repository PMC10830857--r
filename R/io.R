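#' Game presets and configuration files
#'
#' `game_preset()` loads one of the shipped YAML game definitions:
#' `"icg4"` and `"icg6"` (the incremental game with `M = 0.5`, doubling
#' resource and 80% split, at 4 and 6 steps), `"ccg6_synthetic"` (a
#' synthetic constant-size 6-step schedule with an equal split at step 1
#' and a taker share growing linearly to 80%; a stand-in for user-supplied
#' constant-size tables, not an empirical one). `"ccg6_template"` is the
#' empty schedule users fill in from their own source.
#'
#' `load_game_config()` reads any YAML/JSON game definition: either
#' `{variant: incremental, L, M, growth, split}` or
#' `{variant: constant-size|custom-schedule, schedule: [[p1, p2], ...],
#' pass_through: [p1, p2]}`.
#'
#' @param name preset name.
#' @param path path to a YAML game definition.
#' @return a `centipede_game`.
#' @export
game_preset <- function(name = c("icg4", "icg6", "ccg6_synthetic")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"), package = "tomcg",
                      mustWork = TRUE)
  load_game_config(path)
}

#' @rdname game_preset
#' @export
load_game_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  variant <- cfg$variant %||% "incremental"
  if (variant == "incremental") {
    icg(L = cfg$L %||% 4, M = cfg$M %||% 0.5, growth = cfg$growth %||% 2,
        split = cfg$split %||% 0.8)
  } else {
    if (is.null(cfg$schedule) || any(vapply(cfg$schedule, is.null, TRUE)))
      stop("schedule rows missing or empty; fill in the template",
           call. = FALSE)
    sched <- do.call(rbind, lapply(cfg$schedule, as.numeric))
    centipede_game(data.frame(p1 = sched[, 1], p2 = sched[, 2]),
                   pass_through = as.numeric(cfg$pass_through),
                   variant = variant)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run configuration with defaults
#'
#' Reads a YAML/JSON run configuration and fills in the headline defaults
#' (`Z = 500`, `R = 5e4`, `rp = "inertia"`, `eps = 0.19`, `beta = 0.31`,
#' `mu = 0`, `cost = 0`, `seed = 1`), validating ranges.
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file.
#' @return validated named list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    yaml::read_yaml(path)
  }
  cfg[names(overrides)] <- overrides
  out <- list(
    game = cfg$game %||% "icg4",
    rp = cfg$rp %||% "inertia",
    eps = cfg$eps %||% 0.19,
    beta = cfg$beta %||% 0.31,
    Z = cfg$Z %||% 500,
    mu = cfg$mu %||% 0,
    R = cfg$R %||% 5e4,
    cost = cfg$cost %||% 0,
    seed = cfg$seed %||% 1
  )
  if (!out$rp %in% rp_kinds()) stop("unknown rp: ", out$rp, call. = FALSE)
  check_eps(out$eps)
  if (out$beta < 0) stop("beta must be nonnegative", call. = FALSE)
  if (out$Z < 2) stop("Z must be at least 2", call. = FALSE)
  if (out$mu < 0 || out$mu > 1) stop("mu must lie in [0, 1]", call. = FALSE)
  out
}

#' Deterministic tabular output
#'
#' Writes distributions, matrices, trajectories or sweep surfaces as CSV
#' with a fixed column order and 12 significant digits, so identical runs
#' produce byte-identical files. Never-take categories are serialized as
#' `"never"`; matrices carry `"(t,k)"` strategy labels.
#'
#' @param x named probability vector, matrix, or data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  if (is.null(x) || (is.data.frame(x) && !nrow(x)) ||
      (!is.data.frame(x) && !length(x)))
    stop("nothing to write", call. = FALSE)
  fmt <- function(v) if (is.double(v)) signif(v, 12) else v
  if (is.matrix(x)) {
    df <- data.frame(strategy = rownames(x),
                     as.data.frame(apply(x, 2, fmt)),
                     check.names = FALSE)
  } else if (is.data.frame(x)) {
    df <- as.data.frame(lapply(x, fmt))
    names(df) <- names(x)
  } else {
    df <- data.frame(category = names(x), value = fmt(as.numeric(x)))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an empirical ending-step distribution
#'
#' CSV with columns `step` (integers `1..L` and `"pass"`/`"never"` for
#' pass-through) and `count` or `probability`; missing categories get zero
#' mass.
#'
#' @param path CSV path.
#' @param game the `centipede_game` the data refer to.
#' @return normalized probability vector ordered `"1".."L"`, `"pass"`.
#' @export
read_step_distribution <- function(path, game) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!"step" %in% names(df)) stop("need a `step` column", call. = FALSE)
  vcol <- intersect(c("count", "probability", "freq", "frequency"),
                    names(df))
  if (!length(vcol)) stop("need a count or probability column",
                          call. = FALSE)
  v <- as.numeric(df[[vcol[1]]])
  lab <- tolower(as.character(df$step))
  lab[lab %in% c("never", "pass_through", "passthrough")] <- "pass"
  out <- empty_step_dist(game)
  bad <- setdiff(lab, names(out))
  if (length(bad)) stop("unknown step categories: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  out[lab] <- v
  if (any(out < 0) || sum(out) <= 0)
    stop("step distribution must be nonnegative with positive sum",
         call. = FALSE)
  out / sum(out)
}
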