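#' Validate a pipeline configuration file
#'
#' One YAML file drives every stage (simulate, sweep, evaluate, report) so a
#' whole parameter assessment is a reproducible artifact. Sections:
#'
#' \describe{
#'   \item{sources}{List of sources; each needs `id`, `fasta`, `role`
#'     ("endogenous"/"contaminant"), `fraction`; optional `divergence`
#'     (default 0) and `damage`, either `{p0, decay, positions, both_ends}`
#'     (geometric profile) or `{ct5_file, ga3_file}` (mapDamage tables).}
#'   \item{simulation}{`n_reads`; optional `min_length` (30), `decay_length`
#'     (15), `seed` (1), `quality_char` ("I").}
#'   \item{mapper}{`template` (command with `{...}` placeholders), optional
#'     `setup` command and `workdir` (default "runs").}
#'   \item{grid}{Mapping of parameter name to a non-empty value list.}
#'   \item{evaluation}{Optional `mapq_threshold` (30), `tolerance` (0),
#'     `baseline_run`.}
#' }
#'
#' Relative paths are resolved against the config file's directory. All
#' validation failures are reported together, each naming its section and
#' key.
#'
#' @param path Path to the YAML config.
#' @param check_files If `TRUE` (default) referenced FASTA/profile files
#'   must exist.
#' @return Object of class `run_config`: the validated config with defaults
#'   filled in, `sources` as [source_spec()] objects and `grid` as a
#'   [param_grid()].
#' @export
validate_config <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("config parse error in '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (!is.list(raw)) stop("config '", path, "' is not a mapping")
  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || grepl("^/", p)) p else file.path(base_dir, p)
  }
  errs <- character(0)
  note <- function(...) errs <<- c(errs, paste0(...))

  ## [sources]
  sources <- list()
  if (is.null(raw$sources) || !is.list(raw$sources) ||
      length(raw$sources) == 0L) {
    note("[sources]: at least one source is required")
  } else {
    fractions <- numeric(0)
    for (i in seq_along(raw$sources)) {
      s <- raw$sources[[i]]
      lab <- paste0("[sources][", i, "]")
      if (is.null(s$id)) { note(lab, ": missing 'id'"); next }
      lab <- paste0("[sources] '", s$id, "'")
      if (is.null(s$fasta)) { note(lab, ": missing 'fasta'"); next }
      fasta <- resolve(s$fasta)
      if (check_files && !file.exists(fasta)) {
        note(lab, ": fasta file not found: ", fasta); next
      }
      if (is.null(s$role) || !s$role %in% c("endogenous", "contaminant")) {
        note(lab, ": 'role' must be endogenous or contaminant"); next
      }
      if (is.null(s$fraction) || !is.numeric(s$fraction) ||
          s$fraction < 0 || s$fraction > 1) {
        note(lab, ": 'fraction' must be a number in [0, 1]"); next
      }
      div <- if (is.null(s$divergence)) 0 else s$divergence
      if (!is.numeric(div) || div < 0 || div > 1) {
        note(lab, ": 'divergence' must be a number in [0, 1]"); next
      }
      dmg <- NULL
      if (!is.null(s$damage)) {
        d <- s$damage
        if (!is.null(d$ct5_file)) {
          ct5 <- resolve(d$ct5_file)
          ga3 <- resolve(d$ga3_file)
          if (check_files && !file.exists(ct5)) {
            note(lab, ": damage ct5_file not found: ", ct5); next
          }
          dmg <- tryCatch(parse_mapdamage_profile(ct5, ga3),
                          error = function(e) {
                            note(lab, ": ", conditionMessage(e)); NULL
                          })
        } else if (!is.null(d$p0)) {
          dmg <- tryCatch(
            geometric_profile(d$p0,
                              if (is.null(d$decay)) 0.5 else d$decay,
                              if (is.null(d$positions)) 15L else d$positions,
                              both_ends = isTRUE(d$both_ends)),
            error = function(e) { note(lab, ": ", conditionMessage(e)); NULL })
        } else {
          note(lab, ": 'damage' needs either p0/decay/positions or ",
               "ct5_file/ga3_file"); next
        }
      }
      fractions <- c(fractions, s$fraction)
      sources[[length(sources) + 1L]] <-
        list(source_id = s$id, fasta_path = fasta, role = s$role,
             fraction = s$fraction, divergence = div, damage = dmg)
    }
    if (length(fractions) == length(raw$sources) &&
        abs(sum(fractions) - 1) > 1e-9) {
      note("[sources]: fractions must sum to 1 (got ",
           format(sum(fractions)), ")")
    }
  }

  ## [simulation]
  sim <- raw$simulation
  if (is.null(sim) || is.null(sim$n_reads)) {
    note("[simulation]: 'n_reads' is required")
    sim <- list(n_reads = 0L)
  }
  n_reads <- sim$n_reads
  if (!is.numeric(n_reads) || n_reads < 0) {
    note("[simulation]: 'n_reads' must be a non-negative integer")
    n_reads <- 0L
  }
  min_length <- if (is.null(sim$min_length)) 30L else sim$min_length
  decay_length <- if (is.null(sim$decay_length)) 15 else sim$decay_length
  seed <- if (is.null(sim$seed)) 1L else sim$seed
  quality_char <- if (is.null(sim$quality_char)) "I" else sim$quality_char
  if (!is.numeric(min_length) || min_length < 1) {
    note("[simulation]: 'min_length' must be >= 1")
  }
  if (!is.numeric(decay_length) || decay_length < 0) {
    note("[simulation]: 'decay_length' must be >= 0")
  }
  if (!is.character(quality_char) || nchar(quality_char) != 1L) {
    note("[simulation]: 'quality_char' must be a single character")
  }

  ## [mapper]
  mapper <- raw$mapper
  if (!is.null(mapper)) {
    if (is.null(mapper$template) || !nzchar(mapper$template)) {
      note("[mapper]: 'template' is required when [mapper] is present")
    }
    mapper$workdir <- resolve(
      if (is.null(mapper$workdir)) "runs" else mapper$workdir)
  }

  ## [grid]
  grid <- NULL
  if (!is.null(raw$grid)) {
    g <- raw$grid
    if (!is.list(g) || is.null(names(g)) || any(!nzchar(names(g)))) {
      note("[grid]: must map parameter names to value lists")
    } else {
      for (nm in names(g)) {
        if (length(g[[nm]]) == 0L) {
          note("[grid]: parameter '", nm, "' has an empty value list")
        }
      }
      if (length(errs) == 0L) {
        grid <- do.call(param_grid, lapply(g, as.character))
      }
    }
  }

  ## [evaluation]
  ev <- raw$evaluation
  mapq_threshold <- if (is.null(ev$mapq_threshold)) 30L else ev$mapq_threshold
  tolerance <- if (is.null(ev$tolerance)) 0L else ev$tolerance
  if (!is.numeric(mapq_threshold) || mapq_threshold < 0) {
    note("[evaluation]: 'mapq_threshold' must be >= 0")
  }
  if (!is.numeric(tolerance) || tolerance < 0) {
    note("[evaluation]: 'tolerance' must be >= 0")
  }

  if (length(errs) > 0L) {
    stop("invalid config '", path, "':\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }

  specs <- lapply(sources, function(s) {
    source_spec(s$source_id, s$fasta_path, s$role, s$fraction,
                divergence = s$divergence, damage = s$damage)
  })
  structure(list(
    sim = sim_config(specs, n_reads = n_reads, min_length = min_length,
                     decay_length = decay_length, seed = seed,
                     quality_char = quality_char),
    mapper = mapper,
    grid = grid,
    evaluation = list(mapq_threshold = as.integer(mapq_threshold),
                      tolerance = as.integer(tolerance),
                      baseline_run = ev$baseline_run)
  ), class = "run_config")
}
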