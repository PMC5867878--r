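#' Declare a mapper parameter grid
#'
#' A grid is an ordered list of named parameters, each with an ordered list
#' of candidate values. Values are kept as verbatim text so settings like
#' a fractional mismatch value of "0.0001" or a seed length of "1000"
#' (large enough to disable seeding) render into the mapper call exactly as
#' written.
#'
#' @param ... Named arguments; each a vector of candidate values.
#' @return Object of class `param_grid`.
#' @examples
#' param_grid(n = c("0.04", "0.004"), l = c("32", "1000"))
#' @export
param_grid <- function(...) {
  params <- lapply(list(...), as.character)
  if (length(params) > 0L) {
    if (is.null(names(params)) || any(!nzchar(names(params)))) {
      stop("every grid parameter must be named")
    }
    if (anyDuplicated(names(params))) {
      stop("duplicate parameter name: ",
           names(params)[duplicated(names(params))][1L])
    }
    empty <- vapply(params, length, 0L) == 0L
    if (any(empty)) {
      stop("parameter '", names(params)[empty][1L], "' has no values")
    }
  }
  structure(list(parameters = params), class = "param_grid")
}

#' Expand a parameter grid into all value combinations
#'
#' Produces the full Cartesian product in lexicographic order of the
#' declared parameter order: the first parameter varies slowest, the last
#' fastest. An empty grid yields a single empty assignment (a run with the
#' bare command template).
#'
#' @param grid A [param_grid()].
#' @return Data frame of assignments, one row per combination, columns in
#'   declared parameter order; all values character.
#' @export
expand_param_grid <- function(grid) {
  stopifnot(inherits(grid, "param_grid"))
  params <- grid$parameters
  if (length(params) == 0L) {
    return(data.frame(row.names = 1L)[, 0, drop = FALSE])
  }
  # expand.grid varies the FIRST column fastest; feed reversed, then reorder
  g <- expand.grid(rev(params), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g <- g[, rev(seq_along(params)), drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Render a mapper command from a placeholder template
#'
#' Placeholders have the form `{name}` and are substituted verbatim from
#' the parameter assignment and the I/O slots (conventionally `{reads}`,
#' `{reference}`, `{output}`). Rendering fails before anything is executed
#' if a placeholder cannot be resolved; assignment entries that the
#' template never uses produce a warning.
#'
#' @param template Command template text.
#' @param assignment Named list/vector of parameter values for this run.
#' @param io_slots Named list/vector of I/O paths.
#' @return The rendered command string.
#' @examples
#' render_command("bwa aln -n {n} -l {l} {reference} {reads}",
#'                c(n = "0.004", l = "32"),
#'                c(reference = "ref.fa", reads = "sim.fastq"))
#' @export
render_command <- function(template, assignment = character(0),
                           io_slots = character(0)) {
  vals <- c(unlist(assignment), unlist(io_slots))
  used <- character(0)
  cmd <- template
  for (nm in names(vals)) {
    ph <- paste0("{", nm, "}")
    if (grepl(ph, cmd, fixed = TRUE)) used <- c(used, nm)
    cmd <- gsub(ph, vals[[nm]], cmd, fixed = TRUE)
  }
  left <- regmatches(cmd, gregexpr("\\{[A-Za-z0-9_.]+\\}", cmd))[[1L]]
  if (length(left) > 0L) {
    stop("unresolved placeholder(s) in command template: ",
         paste(unique(left), collapse = ", "))
  }
  unused <- setdiff(names(unlist(assignment)), used)
  if (length(unused) > 0L) {
    warning("assignment value(s) unused by the template: ",
            paste(unused, collapse = ", "))
  }
  cmd
}

#' Execute one mapping run
#'
#' Runs the command through the system shell, capturing standard output and
#' error to per-run log files in `workdir` and recording the exit status,
#' wall time, and child CPU time. A non-zero exit is recorded, not raised,
#' so a sweep continues past individual failures.
#'
#' @param command Rendered command string.
#' @param run_id Unique run identifier (log/SAM names derive from it).
#' @param workdir Writable directory for logs.
#' @param sam_path Path the command writes its alignments to (recorded in
#'   the result; the command itself must produce it, e.g. via `{output}`).
#' @return One-row data frame: `run_id`, `command`, `exit_status`,
#'   `wall_time_s`, `cpu_time_s`, `sam_path`.
#' @export
execute_run <- function(command, run_id, workdir, sam_path = NA_character_) {
  if (!dir.exists(workdir)) stop("workdir does not exist: ", workdir)
  if (file.access(workdir, 2L) != 0L) stop("workdir not writable: ", workdir)
  out_log <- file.path(workdir, paste0(run_id, ".stdout.log"))
  err_log <- file.path(workdir, paste0(run_id, ".stderr.log"))
  if (file.exists(out_log) || file.exists(err_log)) {
    stop("run_id '", run_id, "' already used in ", workdir)
  }
  t0 <- proc.time()
  status <- suppressWarnings(
    system2("sh", c("-c", shQuote(command)), stdout = out_log,
            stderr = err_log)
  )
  dt <- proc.time() - t0
  data.frame(run_id = run_id, command = command,
             exit_status = as.integer(status),
             wall_time_s = unname(dt["elapsed"]),
             cpu_time_s = unname(dt["user.child"] + dt["sys.child"]),
             sam_path = sam_path, stringsAsFactors = FALSE)
}

#' Run a full parameter sweep of an external mapper
#'
#' Expands the grid, renders one command per assignment, optionally runs a
#' one-off setup command first (e.g. reference indexing, which does not
#' depend on the swept parameters), and executes the runs sequentially in
#' grid order. Each run gets `{output}` = `<workdir>/<run_id>.sam` unless
#' the caller overrides `output` in `io_slots`. A machine-readable manifest
#' TSV is written to `<workdir>/sweep_manifest.tsv`.
#'
#' @param grid A [param_grid()].
#' @param template Mapper command template with `{...}` placeholders.
#' @param io_slots Named list of I/O paths (`reads`, `reference`, ...).
#' @param workdir Directory for SAM outputs, logs and the manifest.
#' @param setup_command Optional shell command run once before the sweep;
#'   a non-zero exit aborts the sweep with an error.
#' @return The manifest data frame: `run_id`, one column per grid parameter,
#'   `command`, `exit_status`, `wall_time_s`, `cpu_time_s`, `sam_path`.
#' @export
run_sweep <- function(grid, template, io_slots, workdir,
                      setup_command = NULL) {
  if (!dir.exists(workdir)) dir.create(workdir, recursive = TRUE)
  assignments <- expand_param_grid(grid)
  n <- nrow(assignments)
  run_ids <- sprintf("run%03d", seq_len(n))

  # render everything first so placeholder errors precede any execution
  commands <- character(n)
  sam_paths <- character(n)
  for (r in seq_len(n)) {
    asg <- as.list(assignments[r, , drop = FALSE])
    slots <- utils::modifyList(
      list(output = file.path(workdir, paste0(run_ids[r], ".sam"))),
      as.list(io_slots))
    if (is.null(slots$output) || !nzchar(slots$output)) {
      slots$output <- file.path(workdir, paste0(run_ids[r], ".sam"))
    }
    sam_paths[r] <- slots$output
    commands[r] <- render_command(template, asg, slots)
  }

  if (!is.null(setup_command) && nzchar(setup_command)) {
    # setup is parameter-independent (e.g. indexing): render I/O slots only
    setup_command <- render_command(setup_command, io_slots = io_slots)
    setup <- execute_run(setup_command, "setup", workdir)
    if (setup$exit_status != 0L) {
      stop("setup command failed (exit ", setup$exit_status, "); see ",
           file.path(workdir, "setup.stderr.log"))
    }
  }

  runs <- vector("list", n)
  for (r in seq_len(n)) {
    message("[", run_ids[r], "/", n, "] ", commands[r])
    runs[[r]] <- execute_run(commands[r], run_ids[r], workdir,
                             sam_path = sam_paths[r])
  }
  manifest <- cbind(
    data.frame(run_id = run_ids, stringsAsFactors = FALSE),
    assignments,
    do.call(rbind, runs)[, c("command", "exit_status", "wall_time_s",
                             "cpu_time_s", "sam_path")]
  )
  rownames(manifest) <- NULL
  utils::write.table(manifest, file.path(workdir, "sweep_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}

#' Read a sweep manifest written by [run_sweep()]
#' @param path Manifest TSV path.
#' @return Manifest data frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, sep = "\t", header = TRUE,
                         colClasses = "character", check.names = FALSE)
  m$exit_status <- as.integer(m$exit_status)
  m$wall_time_s <- as.numeric(m$wall_time_s)
  m$cpu_time_s <- as.numeric(m$cpu_time_s)
  m
}
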