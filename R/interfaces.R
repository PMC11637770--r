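## Control-file dialect, parameter backends, bpp adapter and run logging --
## the pipeline shell around the gdi engine and the hierarchical algorithms.

.CONTROL_KEYS <- c("output_directory", "seqfile", "Imapfile", "guide_tree",
                   "mode", "GDI_threshold", "threads", "burnin", "sampfreq",
                   "nsample", "migration", "definition", "replicates",
                   "seed", "backend", "param_table", "nonsister",
                   "split_lower", "split_upper")

#' Parse a delimitation control file
#'
#' Plain-text \code{key = value} lines (\code{#} starts a comment; keys
#' shared with bpp use the same syntax).  Required keys:
#' \code{guide_tree} (rooted binary Newick), \code{mode} (\code{merge} or
#' \code{split}) and \code{Imapfile}.  Optional keys: \code{output_directory},
#' \code{seqfile}, \code{GDI_threshold} (merge/split cutoff, default 0.2),
#' \code{threads}, \code{burnin}, \code{sampfreq}, \code{nsample} (MCMC
#' settings passed through to an external inference program),
#' \code{migration} (comma-separated \code{donor>recipient} pairs, each with
#' an optional \code{:rate}), \code{definition} (\code{gdiJ} or
#' \code{gdiK}), \code{replicates}, \code{seed}, \code{backend}
#' (\code{fixed} or \code{external}), \code{param_table} (fixed-backend
#' parameter file), \code{nonsister} (0/1), \code{split_lower},
#' \code{split_upper}.  Unknown keys are rejected by name.
#'
#' @param path control file path.
#' @return validated list of class \code{"ControlConfig"}.
#' @export
parseControl <- function(path) {
  if (!file.exists(path)) stop("control file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed control line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  unknown <- setdiff(keys, .CONTROL_KEYS)
  if (length(unknown))
    stop("unknown control variable(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(keys))
    stop("duplicate control variable: ", keys[duplicated(keys)][1])
  cfg <- as.list(setNames(vals, keys))
  for (req in c("guide_tree", "mode", "Imapfile"))
    if (is.null(cfg[[req]]))
      stop("missing required control variable: ", req)
  if (!cfg$mode %in% c("merge", "split"))
    stop("mode must be 'merge' or 'split', got '", cfg$mode, "'")
  phy <- tryCatch(suppressWarnings(ape::read.tree(text = cfg$guide_tree)),
                  error = function(e) NULL)
  if (is.null(phy) || !ape::is.rooted(phy) || !ape::is.binary(phy))
    stop("guide_tree is not a rooted binary Newick string")
  num <- function(key, default) {
    if (is.null(cfg[[key]])) return(default)
    v <- suppressWarnings(as.numeric(cfg[[key]]))
    if (is.na(v)) stop(key, " must be numeric, got '", cfg[[key]], "'")
    v
  }
  cfg$GDI_threshold <- num("GDI_threshold", 0.2)
  if (cfg$GDI_threshold <= 0 || cfg$GDI_threshold >= 1)
    stop("GDI_threshold must be in (0, 1)")
  cfg$threads <- as.integer(num("threads", 1))
  cfg$burnin <- as.integer(num("burnin", 0))
  cfg$sampfreq <- as.integer(num("sampfreq", 1))
  cfg$nsample <- as.integer(num("nsample", 0))
  cfg$replicates <- num("replicates", 1e5)
  cfg$seed <- if (is.null(cfg$seed)) NULL else as.integer(num("seed", NA))
  cfg$split_lower <- num("split_lower", 0.5)
  cfg$split_upper <- num("split_upper", 0.7)
  cfg$nonsister <- num("nonsister", 0) != 0
  cfg$definition <- if (is.null(cfg$definition)) "gdiK" else cfg$definition
  if (!cfg$definition %in% c("gdiJ", "gdiK"))
    stop("definition must be gdiJ or gdiK")
  cfg$backend <- if (is.null(cfg$backend)) "fixed" else cfg$backend
  if (!cfg$backend %in% c("fixed", "external"))
    stop("backend must be fixed or external")
  cfg$migration <- .parseMigrationSpec(cfg$migration)
  structure(cfg, class = "ControlConfig")
}

.parseMigrationSpec <- function(txt) {
  if (is.null(txt) || !nzchar(txt)) return(migrationEvents())
  parts <- trimws(strsplit(txt, ",", fixed = TRUE)[[1]])
  m <- regmatches(parts,
                  regexec("^([^>:]+)>([^>:]+)(?::([0-9.eE+-]+))?$", parts))
  bad <- lengths(m) == 0 | vapply(m, length, 0L) < 3L
  if (any(bad))
    stop("malformed migration entry: ", parts[bad][1],
         " (expected donor>recipient[:rate])")
  migrationEvents(
    donor = trimws(vapply(m, `[`, "", 2)),
    recipient = trimws(vapply(m, `[`, "", 3)),
    rate = vapply(m, function(g)
      if (length(g) >= 4 && nzchar(g[4])) as.numeric(g[4]) else 0, 0))
}

#' Serialize a control configuration
#'
#' parse -> write -> parse is idempotent.
#'
#' @param cfg a \code{ControlConfig} from [parseControl()].
#' @param path output path.
#' @export
writeControl <- function(cfg, path) {
  stopifnot(inherits(cfg, "ControlConfig"))
  mig <- cfg$migration
  migtxt <- if (nrow(mig) == 0L) NULL else
    paste(sprintf("%s>%s:%g", mig$donor, mig$recipient, mig$rate),
          collapse = ", ")
  out <- c()
  put <- function(key, val) {
    if (!is.null(val) && length(val) == 1L && nzchar(as.character(val)))
      out <<- c(out, sprintf("%s = %s", key, as.character(val)))
  }
  put("output_directory", cfg$output_directory)
  put("seqfile", cfg$seqfile)
  put("Imapfile", cfg$Imapfile)
  put("guide_tree", cfg$guide_tree)
  put("mode", cfg$mode)
  put("GDI_threshold", cfg$GDI_threshold)
  put("threads", cfg$threads)
  put("burnin", cfg$burnin)
  put("sampfreq", cfg$sampfreq)
  put("nsample", cfg$nsample)
  put("migration", migtxt)
  put("definition", cfg$definition)
  put("replicates", cfg$replicates)
  put("seed", cfg$seed)
  put("backend", cfg$backend)
  put("param_table", cfg$param_table)
  put("nonsister", as.integer(cfg$nonsister))
  put("split_lower", cfg$split_lower)
  put("split_upper", cfg$split_upper)
  writeLines(out, path)
  invisible(path)
}

## -- backends ----------------------------------------------------------------

#' Fixed-parameter backend
#'
#' A deterministic backend serving a point parameter vector: whenever the
#' delimitation pipeline asks for parameters of the current model, entries
#' of \code{params} whose names match the model's [paramVector()] names
#' (\code{tau_<label>}, \code{theta_<label>},
#' \code{M_<donor>_<recipient>}) are applied.  With \code{rule =
#' "inherit"} (default) parameters absent from the table -- typically the
#' theta of a freshly merged population -- keep the value inherited through
#' the merge; with \code{rule = "strict"} any missing parameter is an
#' error.
#'
#' @param params named numeric vector, or path to a two-column whitespace
#'   table (name, value).
#' @param rule \code{"inherit"} or \code{"strict"}.
#' @return a backend function \code{model -> model}.
#' @export
fixedBackend <- function(params, rule = c("inherit", "strict")) {
  rule <- match.arg(rule)
  if (is.character(params) && length(params) == 1L) {
    tab <- utils::read.table(params, header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("name", "value"))
    params <- setNames(as.numeric(tab$value), tab$name)
  }
  stopifnot(is.numeric(params), !is.null(names(params)))
  function(model) {
    pv <- paramVector(model)
    if (rule == "strict") {
      missing <- setdiff(names(pv), names(params))
      if (length(missing))
        stop("fixed backend lacks parameter(s) for the proposed model: ",
             paste(missing, collapse = ", "))
    }
    updateModelParams(model, params[intersect(names(params), names(pv))])
  }
}

#' Backend from a posterior sample table
#'
#' Serves the posterior means of the sampled parameters as a point
#' backend; the full draw table is attached as
#' \code{attr(backend, "samples")} for use with [posteriorGdi()].
#'
#' @param samples data.frame of draws (see [readPosteriorSample()]).
#' @return a backend function \code{model -> model}.
#' @export
posteriorBackend <- function(samples) {
  stopifnot(is.data.frame(samples), nrow(samples) >= 1L)
  means <- vapply(samples, mean, 0)
  be <- fixedBackend(means, rule = "inherit")
  attr(be, "samples") <- samples
  be
}

## -- external inference adapter ---------------------------------------------

#' Write control and Imap files for an external MSC-M inference program
#'
#' Generates, for the current delimitation, the control file and Imap file
#' needed to drive a bpp-style MCMC run estimating the model parameters
#' from sequence data.  Nothing is executed; see [bppAdapter()] for turning
#' a (possibly pre-recorded) run directory into a backend.
#'
#' @param model current [MSCMModel-class].
#' @param imap named character vector (individual -> population); remapped
#'   onto the current tips before writing.
#' @param cfg a \code{ControlConfig}.
#' @param dir output directory (created if needed).
#' @return invisible list of written paths.
#' @export
writeBppFiles <- function(model, imap, cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tips <- tipLabels(model)
  imap_path <- file.path(dir, "current.Imap.txt")
  writeImap(imap, imap_path)
  counts <- table(factor(imap, levels = tips))
  mig <- migrations(model)
  ctl <- c(
    sprintf("seqfile = %s", if (is.null(cfg$seqfile)) "" else cfg$seqfile),
    sprintf("Imapfile = %s", imap_path),
    "outfile = out.txt",
    "mcmcfile = mcmc.txt",
    sprintf("species&tree = %d %s", length(tips), paste(tips, collapse = " ")),
    paste(" ", paste(as.integer(counts), collapse = " ")),
    paste(" ", newickString(model)),
    if (nrow(mig)) c(sprintf("migration = %d", nrow(mig)),
                     sprintf("  %s %s", mig$donor, mig$recipient)),
    sprintf("burnin = %d", cfg$burnin),
    sprintf("sampfreq = %d", cfg$sampfreq),
    sprintf("nsample = %d", cfg$nsample))
  ctl_path <- file.path(dir, "current.bpp.ctl")
  writeLines(ctl, ctl_path)
  invisible(list(control = ctl_path, imap = imap_path))
}

#' Backend adapter around an external inference run directory
#'
#' Returns a backend that, when asked for parameters, reads the MCMC sample
#' table from \code{dir} (optionally invoking \code{run} first to produce
#' it) and applies the posterior means to the model.  With \code{run =
#' NULL} the adapter replays a pre-recorded output directory, which is how
#' the test suite exercises it without shelling out.
#'
#' @param dir directory containing the MCMC output.
#' @param mcmcfile file name of the sample table within \code{dir}.
#' @param run optional function \code{(model, dir) -> NULL} invoking the
#'   external program.
#' @return a backend function \code{model -> model} with the draw table in
#'   \code{attr(, "samples")} after the first call.
#' @export
bppAdapter <- function(dir, mcmcfile = "mcmc.txt", run = NULL) {
  force(dir); force(mcmcfile); force(run)
  env <- new.env(parent = emptyenv())
  be <- function(model) {
    if (!is.null(run)) run(model, dir)
    path <- file.path(dir, mcmcfile)
    if (!file.exists(path))
      stop("external inference output not found: ", path)
    samples <- readPosteriorSample(path)
    env$samples <- samples
    means <- vapply(samples, mean, 0)
    updateModelParams(model, means[intersect(names(means),
                                             names(paramVector(model)))])
  }
  attr(be, "samples") <- function() env$samples
  be
}

## -- pipeline ----------------------------------------------------------------

#' Run a delimitation analysis from a control file
#'
#' Builds the guide model from the control file's \code{guide_tree},
#' \code{migration} specification and the fixed-backend parameter table
#' (\code{param_table}, entries named as in [paramVector()]), reads and
#' validates the Imap, and runs the hierarchical merge or split algorithm.
#' When an \code{output_directory} is set, the per-iteration log
#' (\code{delimitation_log.tsv}) and the final delimitation
#' (\code{final_delimitation.txt}: species list and Newick tree) are
#' written there.
#'
#' @param control path to a control file, or a parsed \code{ControlConfig}.
#' @param backend optional backend overriding the control file's choice.
#' @return final [DelimitationState-class] (invisibly, with the report in
#'   \code{attr(, "report")}).
#' @export
runDelimitationFromControl <- function(control, backend = NULL) {
  cfg <- if (inherits(control, "ControlConfig")) control
         else parseControl(control)
  params <- if (!is.null(cfg$param_table)) {
    tab <- utils::read.table(cfg$param_table, header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("name", "value"))
    setNames(as.numeric(tab$value), tab$name)
  } else numeric()
  tau <- params[startsWith(names(params), "tau_")]
  names(tau) <- sub("^tau_", "", names(tau))
  theta <- params[startsWith(names(params), "theta_")]
  names(theta) <- sub("^theta_", "", names(theta))
  if (!length(theta))
    stop("param_table must provide theta_<label> entries for the guide tree")
  model <- parseGuideTree(cfg$guide_tree, tau = tau, theta = theta,
                          migration = cfg$migration)
  if (nrow(cfg$migration)) {
    mrates <- params[startsWith(names(params), "M_")]
    if (length(mrates)) model <- updateModelParams(model, mrates)
  }
  if (file.exists(cfg$Imapfile)) readImap(cfg$Imapfile, model)
  if (is.null(backend)) {
    backend <- if (cfg$backend == "fixed" && length(params))
      fixedBackend(params)
    else if (cfg$backend == "external" && !is.null(cfg$output_directory))
      bppAdapter(cfg$output_directory)
    else NULL
  }
  st <- runDelimitation(
    model, mode = cfg$mode,
    thresholds = gdiThresholds(merge = cfg$GDI_threshold,
                               splitUpper = cfg$split_upper,
                               splitLower = cfg$split_lower),
    engine = gdiEngine(definition = cfg$definition,
                       reps = cfg$replicates, seed = cfg$seed),
    backend = backend, nonsister = cfg$nonsister)
  rep <- delimitationReport(st)
  if (!is.null(cfg$output_directory)) {
    dir.create(cfg$output_directory, showWarnings = FALSE, recursive = TRUE)
    writeDelimitationLog(st, file.path(cfg$output_directory,
                                       "delimitation_log.tsv"))
    writeLines(c(sprintf("species: %s",
                         paste(names(rep$species), collapse = " ")),
                 rep$newick),
               file.path(cfg$output_directory, "final_delimitation.txt"))
  }
  attr(st, "report") <- rep
  invisible(st)
}

#' Final delimitation report
#'
#' @param state a [DelimitationState-class].
#' @return list with \code{species} (named list of member populations),
#'   \code{newick} (final species tree) and \code{log}.
#' @export
delimitationReport <- function(state) {
  sp <- speciesAssignment(state)
  newick <- if (length(sp) == 1L) paste0(names(sp), ";")
            else if (setequal(unique(state@assignment),
                              tipLabels(state@model)))
              newickString(state@model@tree)
            else newickString(.collapseModel(state@guide,
                                             state@assignment)@tree)
  list(species = sp, newick = newick, log = state@log)
}

#' Write the iteration log as TSV
#' @param state a [DelimitationState-class].
#' @param path output path.
#' @export
writeDelimitationLog <- function(state, path) {
  utils::write.table(state@log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
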