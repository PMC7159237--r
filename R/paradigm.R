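#' Stimulation schedule parameters
#'
#' Parameters of a fast periodic visual stimulation (FPVS) oddball sequence:
#' stimuli are presented at `base_freq` (Hz) and every `oddball_period`-th
#' stimulus is an identity oddball, so the identity-change rate is
#' `base_freq / oddball_period` (4/7 = 0.571 Hz with the defaults).
#'
#' @param base_freq Stimulation rate in Hz.
#' @param oddball_period Number of stimuli per identity-change cycle.
#' @param seq_duration Full-contrast stimulation length in seconds;
#'   `seq_duration * base_freq` must be a positive integer.
#' @param fade_duration Contrast ramp length in seconds at each end.
#' @param n_face_exemplars,n_name_exemplars Exemplar pool sizes per base
#'   identity.
#' @param n_oddball_identities Number of distinct oddball identities
#'   (one stimulus each).
#' @param size_steps Number of equidistant size scales spanning
#'   `size_min`..`size_max`.
#' @param size_min,size_max Bounds of the size-scale grid (unitless).
#' @param oddball_phase Phase offset of the first oddball in stimuli
#'   (0 puts the first oddball at 0-based index `oddball_period - 1`).
#' @return An object of class `fpvs_schedule_params`.
#' @export
schedule_params <- function(base_freq = 4, oddball_period = 7,
                            seq_duration = 60, fade_duration = 2,
                            n_face_exemplars = 18, n_name_exemplars = 18,
                            n_oddball_identities = 36,
                            size_steps = 5, size_min = 0.8, size_max = 1.2,
                            oddball_phase = 0) {
  if (base_freq <= 0) stop("base_freq must be > 0")
  if (oddball_period < 2) stop("oddball_period must be >= 2")
  n_events <- seq_duration * base_freq
  if (n_events <= 0 || abs(n_events - round(n_events)) > 1e-9)
    stop("seq_duration * base_freq must be a positive integer stimulus count")
  if (size_min >= size_max) stop("size_min must be < size_max")
  if (n_face_exemplars < 1 || n_name_exemplars < 1 || n_oddball_identities < 1)
    stop("stimulus pools must be non-empty")
  if (oddball_phase < 0 || oddball_phase >= oddball_period)
    stop("oddball_phase must lie in [0, oddball_period)")
  structure(list(
    base_freq = base_freq, oddball_period = oddball_period,
    seq_duration = seq_duration, fade_duration = fade_duration,
    n_face_exemplars = n_face_exemplars, n_name_exemplars = n_name_exemplars,
    n_oddball_identities = n_oddball_identities,
    size_steps = size_steps, size_min = size_min, size_max = size_max,
    oddball_phase = oddball_phase,
    n_events = as.integer(round(n_events)),
    oddball_freq = base_freq / oddball_period
  ), class = "fpvs_schedule_params")
}

size_grid <- function(params) {
  seq(params$size_min, params$size_max, length.out = params$size_steps)
}

oddball_indices <- function(params) {
  seq.int(params$oddball_period - 1 + params$oddball_phase,
          params$n_events - 1, by = params$oddball_period)
}

#' Build a stimulation schedule
#'
#' Generates the timed event sequence of one FPVS sequence in one of three
#' conditions: `FN` (Face Name: faces and names of the base identity),
#' `FO` (Face Only: base faces kept, base names replaced by other famous
#' names) or `NO` (Name Only: the mirror). Every `oddball_period`-th
#' stimulus is an identity oddball drawn from a separate pool and shown
#' either as a face or as a name. Modality of every slot, exemplars and
#' size scales are fair seeded draws; the same exemplar never repeats on
#' consecutive stimuli.
#'
#' @param params A [schedule_params()] object.
#' @param condition `"FN"`, `"FO"` or `"NO"`.
#' @param base_identity Label of the base identity.
#' @param seed Integer seed fixing all draws.
#' @return An object of class `fpvs_schedule` with an `events` data frame
#'   (columns `index`, `onset`, `modality`, `identity`, `exemplar`,
#'   `is_oddball`, `size_scale`).
#' @export
build_schedule <- function(params, condition = c("FN", "FO", "NO"),
                           base_identity = "BASE1", seed = 1L) {
  condition <- match.arg(condition)
  stopifnot(inherits(params, "fpvs_schedule_params"))
  n <- params$n_events
  rng <- local_rng(seed)
  odd_idx <- oddball_indices(params)
  is_odd <- rep(FALSE, n)
  is_odd[odd_idx + 1L] <- TRUE

  modality <- ifelse(rng$draw(n) < 0.5, "face", "name")
  sizes <- size_grid(params)[rng$draw_int(n, params$size_steps)]

  odd_pool <- sprintf("ODD%02d", seq_len(params$n_oddball_identities))
  ctrl_face_pool <- sprintf("CTRLFACE%02d", seq_len(params$n_face_exemplars))
  ctrl_name_pool <- sprintf("CTRLNAME%02d", seq_len(params$n_name_exemplars))

  identity <- character(n)
  exemplar <- character(n)
  prev_key <- ""
  for (i in seq_len(n)) {
    if (is_odd[i]) {
      # oddball identities have a single stimulus each; avoid immediate repeats
      repeat {
        id <- odd_pool[rng$draw_int(1, length(odd_pool))]
        key <- paste(modality[i], id, "1")
        if (key != prev_key) break
      }
      identity[i] <- id
      exemplar[i] <- "1"
    } else {
      base_slot <- switch(condition,
        FN = TRUE,
        FO = modality[i] == "face",
        NO = modality[i] == "name")
      if (base_slot) {
        pool_n <- if (modality[i] == "face") params$n_face_exemplars
                  else params$n_name_exemplars
        repeat {
          ex <- as.character(rng$draw_int(1, pool_n))
          key <- paste(modality[i], base_identity, ex)
          if (key != prev_key) break
        }
        identity[i] <- base_identity
        exemplar[i] <- ex
      } else {
        pool <- if (modality[i] == "face") ctrl_face_pool else ctrl_name_pool
        repeat {
          id <- pool[rng$draw_int(1, length(pool))]
          key <- paste(modality[i], id, "1")
          if (key != prev_key) break
        }
        identity[i] <- id
        exemplar[i] <- "1"
      }
    }
    prev_key <- paste(modality[i], identity[i], exemplar[i])
  }

  events <- data.frame(
    index = 0:(n - 1L),
    onset = (0:(n - 1L)) / params$base_freq,
    modality = modality,
    identity = identity,
    exemplar = exemplar,
    is_oddball = is_odd,
    size_scale = sizes,
    stringsAsFactors = FALSE
  )
  structure(list(params = params, condition = condition,
                 base_identity = base_identity, seed = seed, events = events),
            class = "fpvs_schedule")
}

#' Summarise and validate a stimulation schedule
#'
#' Counts events per modality and identity, lists oddball positions, and
#' checks every schedule invariant: oddball periodicity, onset grid, size
#' grid membership, oddballs never carrying the base identity, and the
#' condition-specific identity placement (all base slots carry the base
#' identity in FN; in FO only face base slots do and name base slots must
#' not, and mirrored in NO).
#'
#' @param schedule An `fpvs_schedule`.
#' @return A list with `counts`, `oddball_indices`, and a `violations`
#'   data frame (zero rows for a well-formed schedule).
#' @export
schedule_report <- function(schedule) {
  stopifnot(inherits(schedule, "fpvs_schedule"))
  ev <- schedule$events
  p <- schedule$params
  viol <- list()
  add_viol <- function(type, index) {
    viol[[length(viol) + 1L]] <<- data.frame(type = type, index = index)
  }

  expect_odd <- rep(FALSE, nrow(ev))
  expect_odd[oddball_indices(p) + 1L] <- TRUE
  bad <- which(ev$is_oddball != expect_odd)
  if (length(bad)) add_viol("oddball_periodicity", ev$index[bad])

  bad <- which(abs(ev$onset - ev$index / p$base_freq) > 1e-9)
  if (length(bad)) add_viol("onset_grid", ev$index[bad])

  grid <- size_grid(p)
  bad <- which(vapply(ev$size_scale,
                      function(s) min(abs(s - grid)) > 1e-9, logical(1)))
  if (length(bad)) add_viol("size_grid", ev$index[bad])

  bad <- which(ev$is_oddball & ev$identity == schedule$base_identity)
  if (length(bad)) add_viol("oddball_base_identity", ev$index[bad])

  base_req <- switch(schedule$condition,
    FN = !ev$is_oddball,
    FO = !ev$is_oddball & ev$modality == "face",
    NO = !ev$is_oddball & ev$modality == "name")
  bad <- which(base_req & ev$identity != schedule$base_identity)
  if (length(bad)) add_viol("missing_base_identity", ev$index[bad])
  nonbase_req <- switch(schedule$condition,
    FN = rep(FALSE, nrow(ev)),
    FO = !ev$is_oddball & ev$modality == "name",
    NO = !ev$is_oddball & ev$modality == "face")
  bad <- which(nonbase_req & ev$identity == schedule$base_identity)
  if (length(bad)) add_viol("base_identity_in_control_slot", ev$index[bad])

  violations <- if (length(viol)) do.call(rbind, viol)
                else data.frame(type = character(0), index = integer(0))
  list(
    counts = list(
      n_events = nrow(ev),
      n_oddballs = sum(ev$is_oddball),
      modality = table(ev$modality),
      modality_nonoddball = table(ev$modality[!ev$is_oddball]),
      identities = table(ev$identity)
    ),
    oddball_indices = ev$index[ev$is_oddball],
    violations = violations,
    n_violations = nrow(violations)
  )
}

#' Write / read a schedule as delimited text
#'
#' One event per row, tab-separated; parameters and condition are stored in
#' `#`-prefixed header lines so that the round trip is lossless.
#'
#' @param schedule An `fpvs_schedule`.
#' @param path Output file path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule`
#'   returns the reconstructed `fpvs_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  p <- schedule$params
  hdr <- c(
    sprintf("# condition=%s base_identity=%s seed=%d",
            schedule$condition, schedule$base_identity, schedule$seed),
    sprintf(paste0("# base_freq=%.10g oddball_period=%d seq_duration=%.10g",
                   " fade_duration=%.10g n_face_exemplars=%d",
                   " n_name_exemplars=%d n_oddball_identities=%d",
                   " size_steps=%d size_min=%.10g size_max=%.10g",
                   " oddball_phase=%d"),
            p$base_freq, p$oddball_period, p$seq_duration, p$fade_duration,
            p$n_face_exemplars, p$n_name_exemplars, p$n_oddball_identities,
            p$size_steps, p$size_min, p$size_max, p$oddball_phase)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(schedule$events, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  if (length(hdr) < 2) stop("malformed schedule file: missing header")
  kv <- function(line) {
    parts <- strsplit(sub("^# *", "", line), " ")[[1]]
    out <- list()
    for (p in parts) {
      s <- strsplit(p, "=", fixed = TRUE)[[1]]
      out[[s[1]]] <- s[2]
    }
    out
  }
  h1 <- kv(hdr[1]); h2 <- kv(hdr[2])
  params <- schedule_params(
    base_freq = as.numeric(h2$base_freq),
    oddball_period = as.integer(h2$oddball_period),
    seq_duration = as.numeric(h2$seq_duration),
    fade_duration = as.numeric(h2$fade_duration),
    n_face_exemplars = as.integer(h2$n_face_exemplars),
    n_name_exemplars = as.integer(h2$n_name_exemplars),
    n_oddball_identities = as.integer(h2$n_oddball_identities),
    size_steps = as.integer(h2$size_steps),
    size_min = as.numeric(h2$size_min),
    size_max = as.numeric(h2$size_max),
    oddball_phase = as.integer(h2$oddball_phase))
  events <- utils::read.delim(textConnection(lines[!startsWith(lines, "#")]),
                              sep = "\t", stringsAsFactors = FALSE)
  events$exemplar <- as.character(events$exemplar)
  structure(list(params = params, condition = h1$condition,
                 base_identity = h1$base_identity, seed = as.integer(h1$seed),
                 events = events),
            class = "fpvs_schedule")
}

# Seeded draw helper: isolates RNG state from the caller.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  }
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- f()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(
    draw = function(n) with_state(function() stats::runif(n)),
    draw_int = function(n, k) with_state(function() sample.int(k, n, replace = TRUE)),
    draw_norm = function(n) with_state(function() stats::rnorm(n))
  )
}
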