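#' Read a vertical-excitation table
#'
#' Reads delimited text with columns \code{snapshot_id}, \code{state},
#' \code{energy_eV}, \code{osc_strength} (optionally \code{depth_nm},
#' \code{tilt_deg}) into an \code{ExcitationSet}. Malformed rows are
#' reported with their line numbers.
#'
#' @param path CSV file path.
#' @param kind "emission" or "absorption".
#' @return an \code{ExcitationSet}.
#' @export
readExcitationTable <- function(path, kind = c("emission", "absorption")) {
  kind <- match.arg(kind)
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e)
                    stop("schema error reading '", path, "': ",
                         conditionMessage(e)))
  need <- c("snapshot_id", "state", "energy_eV", "osc_strength")
  if (!all(need %in% names(tab)))
    stop("schema error: missing column(s) ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  if (nrow(tab) == 0L) stop("schema error: table has no data rows")
  # line numbers: header is line 1
  bad <- which(!is.finite(tab$energy_eV) | tab$energy_eV <= 0 |
                 !is.finite(tab$osc_strength) | tab$osc_strength < 0 |
                 !is.finite(tab$state) | tab$state < 1)
  if (length(bad))
    stop("validation error at line(s) ",
         paste(bad + 1L, collapse = ", "),
         ": energies must be > 0, oscillator strengths >= 0, states >= 1")
  rec <- data.frame(snapshot = tab$snapshot_id,
                    state = as.integer(tab$state),
                    energy_eV = tab$energy_eV,
                    osc_strength = tab$osc_strength,
                    stringsAsFactors = FALSE)
  for (col in c("depth_nm", "tilt_deg"))
    if (col %in% names(tab)) rec[[col]] <- tab[[col]]
  new("ExcitationSet", records = rec, kind = kind)
}

#' Write a vertical-excitation table
#'
#' @param x an \code{ExcitationSet}.
#' @param path CSV file path.
#' @return invisibly, the path.
#' @export
writeExcitationTable <- function(x, path) {
  stopifnot(is(x, "ExcitationSet"))
  r <- records(x)
  out <- data.frame(snapshot_id = r$snapshot, state = r$state,
                    energy_eV = r$energy_eV,
                    osc_strength = r$osc_strength)
  for (col in c("depth_nm", "tilt_deg"))
    if (col %in% names(r)) out[[col]] <- r[[col]]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# registry of external electronic-structure engine adapters
.engines <- new.env(parent = emptyenv())

#' Register an external TD-DFT engine adapter
#'
#' The pipeline delegates all electronic-structure work to a registered
#' adapter: a function taking the run specification (a list with elements
#' \code{molecule}, \code{functional}, \code{basis}, \code{nStates},
#' \code{pointCharges}) and returning a data.frame with columns
#' \code{state}, \code{energy_eV}, \code{osc_strength}. The pipeline never
#' interprets engine internals.
#'
#' @param name adapter name.
#' @param fun adapter function, or NULL to unregister.
#' @return invisibly, the adapter name.
#' @export
registerEngine <- function(name, fun) {
  if (is.null(fun)) {
    if (exists(name, envir = .engines)) rm(list = name, envir = .engines)
    return(invisible(name))
  }
  stopifnot(is.function(fun))
  assign(name, fun, envir = .engines)
  invisible(name)
}

#' @rdname registerEngine
#' @export
listEngines <- function() sort(ls(envir = .engines))

#' Build an adapter from a shell command template
#'
#' Convenience wrapper declaring an engine as a command template with
#' placeholders \code{{molecule}}, \code{{functional}}, \code{{basis}},
#' \code{{nstates}}, \code{{pointcharges}} and \code{{output}}; the command
#' must write a CSV with columns \code{state}, \code{energy_eV},
#' \code{osc_strength} to \code{{output}}.
#'
#' @param template command template string.
#' @return an adapter function suitable for \code{\link{registerEngine}}.
#' @export
commandEngine <- function(template) {
  force(template)
  function(spec) {
    out <- tempfile(fileext = ".csv")
    cmd <- template
    subs <- c(molecule = spec$molecule %||% "",
              functional = spec$functional %||% "",
              basis = spec$basis %||% "",
              nstates = as.character(spec$nStates %||% 5L),
              pointcharges = spec$pointCharges %||% "",
              output = out)
    for (key in names(subs))
      cmd <- gsub(paste0("{", key, "}"), subs[[key]], cmd, fixed = TRUE)
    status <- system(cmd)
    if (status != 0L || !file.exists(out))
      stop("adapter error: command failed (exit ", status, ")")
    tab <- utils::read.csv(out, stringsAsFactors = FALSE)
    need <- c("state", "energy_eV", "osc_strength")
    if (!all(need %in% names(tab)))
      stop("adapter error: output lacks column(s) ",
           paste(setdiff(need, names(tab)), collapse = ", "))
    tab
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a registered engine on a molecule
#'
#' Invokes the named adapter and tags its parsed transitions with the run's
#' functional, basis and environment label, yielding benchmark-comparable
#' entries.
#'
#' @param engine registered adapter name.
#' @param molecule path to the molecule geometry (XYZ).
#' @param functional functional name (passed through).
#' @param basis basis-set name (passed through).
#' @param nStates number of excited states requested.
#' @param pointCharges optional point-charge file path; when given, the
#'   run is an electrostatic-embedding calculation.
#' @param environment environment label for the entries ("gas",
#'   "water-COSMO", "cyclohexane-COSMO", or e.g. "membrane-charges").
#' @return data.frame of benchmark entries: \code{functional},
#'   \code{basis}, \code{environment}, \code{state}, \code{energy_eV},
#'   \code{osc_strength}.
#' @export
runEngine <- function(engine, molecule, functional = "PBE0",
                      basis = "cc-pVDZ", nStates = 5L,
                      pointCharges = NULL, environment = "gas") {
  if (!exists(engine, envir = .engines))
    stop("configuration error: no engine adapter registered as '",
         engine, "'")
  fun <- get(engine, envir = .engines)
  res <- fun(list(molecule = molecule, functional = functional,
                  basis = basis, nStates = as.integer(nStates),
                  pointCharges = pointCharges))
  need <- c("state", "energy_eV", "osc_strength")
  if (!is.data.frame(res) || !all(need %in% names(res)))
    stop("adapter error: adapter must return columns ",
         paste(need, collapse = ", "))
  data.frame(functional = functional, basis = basis,
             environment = environment,
             state = as.integer(res$state),
             energy_eV = res$energy_eV,
             osc_strength = res$osc_strength,
             stringsAsFactors = FALSE)
}

#' Packaged vertical-excitation benchmark tables
#'
#' Reference vertical excitation energies (eV) and oscillator strengths of
#' the methyl-truncated fluorophore for the first five excited states,
#' across two hybrid functionals and four basis sets, in the gas phase and
#' in implicit-solvent (COSMO) water and cyclohexane.
#'
#' @param environment optional filter: "gas", "water-COSMO" or
#'   "cyclohexane-COSMO".
#' @return data.frame with columns \code{functional}, \code{basis},
#'   \code{environment}, \code{state}, \code{energy_eV},
#'   \code{osc_strength}.
#' @export
referenceBenchmarks <- function(environment = NULL) {
  path <- system.file("extdata", "vertical_excitation_benchmarks.csv",
                      package = "ProbeSpectra", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(environment)) tab <- tab[tab$environment %in% environment, ]
  tab
}

#' Compare engine results against a reference benchmark table
#'
#' Joins entries and reference on (functional, basis, environment, state)
#' and reports signed deltas and pass flags at the given tolerances. With
#' \code{stateMatching = "energy"} states are paired by energy order within
#' each (functional, basis, environment) group instead of by index, which
#' is robust to near-degenerate state swaps between codes. Keys present in
#' only one table are reported as untested, not as failures.
#'
#' @param entries data.frame of computed entries (as from
#'   \code{\link{runEngine}}).
#' @param reference reference table (default the packaged benchmarks).
#' @param tolEnergy energy tolerance, eV.
#' @param tolF oscillator-strength tolerance.
#' @param stateMatching "index" or "energy".
#' @return data.frame report with one row per reference entry in the
#'   compared groups: key columns, \code{ref_energy_eV},
#'   \code{energy_eV}, \code{delta_energy_eV}, \code{ref_f}, \code{f},
#'   \code{delta_f}, \code{status} ("pass", "fail" or "untested").
#' @export
compareToBenchmark <- function(entries, reference = referenceBenchmarks(),
                               tolEnergy = 0.02, tolF = 0.02,
                               stateMatching = c("index", "energy")) {
  stateMatching <- match.arg(stateMatching)
  keyCols <- c("functional", "basis", "environment")
  refKey <- do.call(paste, reference[keyCols])
  entKey <- do.call(paste, entries[keyCols])
  common <- intersect(unique(refKey), unique(entKey))
  if (!length(common)) {
    warning("no (functional, basis, environment) groups in common")
    return(data.frame())
  }
  out <- list()
  for (grp in common) {
    ref <- reference[refKey == grp, , drop = FALSE]
    ent <- entries[entKey == grp, , drop = FALSE]
    if (stateMatching == "energy") {
      ref <- ref[order(ref$energy_eV), , drop = FALSE]
      ent <- ent[order(ent$energy_eV), , drop = FALSE]
      m <- seq_len(min(nrow(ref), nrow(ent)))
      ref$matched <- c(m, rep(NA, nrow(ref) - length(m)))
      idx <- ref$matched
    } else {
      idx <- match(ref$state, ent$state)
    }
    dE <- ent$energy_eV[idx] - ref$energy_eV
    dF <- ent$osc_strength[idx] - ref$osc_strength
    status <- ifelse(is.na(idx), "untested",
                     ifelse(abs(dE) <= tolEnergy & abs(dF) <= tolF,
                            "pass", "fail"))
    out[[grp]] <- data.frame(
      functional = ref$functional, basis = ref$basis,
      environment = ref$environment, state = ref$state,
      ref_energy_eV = ref$energy_eV, energy_eV = ent$energy_eV[idx],
      delta_energy_eV = dE,
      ref_f = ref$osc_strength, f = ent$osc_strength[idx],
      delta_f = dF, status = status,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
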