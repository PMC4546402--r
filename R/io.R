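# Readers and writers: CA-only PDB (single and multi-model), CSV tables,
# YAML configs.

chain_ids <- function(n) LETTERS[seq_len(n)]

pdb_fields <- function(ens_map, specs) {
  helices <- unique(ens_map$helix)
  seqs <- lapply(specs, function(s) strsplit(s$sequence, "")[[1]])
  aa3 <- vapply(seq_len(nrow(ens_map)), function(i) {
    sp <- specs[[ens_map$helix[i]]]
    bio3d::aa123(seqs[[ens_map$helix[i]]][ens_map$resno[i] - sp$start_resnum + 1])
  }, character(1))
  list(resid = aa3,
       chain = chain_ids(length(helices))[match(ens_map$helix, helices)],
       resno = ens_map$resno)
}

#' Write a bundle ensemble (or single conformation) as a CA-only PDB
#'
#' ATOM records carry CA atoms only, chains A-D for TM1-TM4, occupancy
#' 1.00, element C. Multiple conformations are written as MODEL/ENDMDL
#' blocks.
#'
#' @param x A `bundle_ensemble` or `bundle_conformation`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_bundle_pdb <- function(x, file) {
  if (inherits(x, "bundle_conformation")) {
    map <- bundle_map(x); specs <- x$specs
    xyz <- matrix(as.vector(t(bundle_coords(x))), nrow = 1)
  } else if (inherits(x, "bundle_ensemble")) {
    map <- x$map; specs <- x$specs; xyz <- x$xyz
  } else stop("x must be a bundle_conformation or bundle_ensemble")
  f <- pdb_fields(map, specs)
  n <- nrow(map)
  bio3d::write.pdb(file = file, xyz = xyz,
                   resno = f$resno, resid = f$resid, chain = f$chain,
                   elety = rep("CA", n), o = rep(1, n), b = rep(0, n),
                   elesy = rep("C", n))
  invisible(file)
}

#' Read a CA-only (multi-model) PDB into a bundle ensemble
#'
#' @param file PDB path.
#' @param specs Helix definitions matching the file's chains (chain A =
#'   first spec, etc.).
#' @return A `bundle_ensemble`.
#' @export
read_bundle_pdb <- function(file, specs = btl_helix_specs()) {
  if (!file.exists(file)) stop("no such file: ", file)
  pdb <- tryCatch(bio3d::read.pdb(file, multi = TRUE),
                  error = function(e)
                    stop("failed to parse PDB '", file, "': ",
                         conditionMessage(e)))
  ca <- bio3d::atom.select(pdb, elety = "CA")
  template <- build_bundle(specs)
  map <- bundle_map(template)
  if (length(ca$atom) != nrow(map))
    stop("PDB '", file, "' has ", length(ca$atom),
         " CA atoms but the helix specs define ", nrow(map))
  xyz <- pdb$xyz[, ca$xyz, drop = FALSE]
  structure(list(xyz = unclass(xyz), scores = numeric(nrow(xyz)),
                 transforms = vector("list", nrow(xyz)),
                 map = map, specs = specs, template = template,
                 acceptance_rate = NA_real_, config = NULL),
            class = "bundle_ensemble")
}

read_csv_schema <- function(file, required, what) {
  if (!file.exists(file)) stop("no such file: ", file)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " '", file, "': missing column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Read a per-residue 15N relaxation CSV
#'
#' Required columns: `residue`, `R1`, `R2`, `NOE`; optional `R1_err`,
#' `R2_err`, `NOE_err`.
#' @param file CSV path.
#' @return `data.frame`.
#' @export
read_relaxation_csv <- function(file) {
  read_csv_schema(file, c("residue", "R1", "R2", "NOE"),
                  "relaxation table")
}

#' Read a FRET titration CSV
#'
#' Required columns: `conc_uM`, `ratio`; optional `err`.
#' @param file CSV path.
#' @return `data.frame`.
#' @export
read_titration_csv <- function(file) {
  read_csv_schema(file, c("conc_uM", "ratio"), "titration table")
}

#' Read helix definitions from a YAML or JSON config
#'
#' The config is a list of helix entries with fields `name`, `sequence`,
#' `start`, `end`, `allowed_axes`, `n_term` (and optionally `synthetic`,
#' ignored here but kept for provenance).
#'
#' @param file Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of [helix_spec()] objects.
#' @export
read_helix_config <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  cfg <- if (grepl("\\.json$", file, ignore.case = TRUE))
    jsonlite::read_json(file, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(file)
  entries <- if (!is.null(cfg$helices)) cfg$helices else cfg
  specs <- lapply(entries, function(e) {
    need <- c("name", "sequence", "start", "end")
    miss <- setdiff(need, names(e))
    if (length(miss))
      stop("helix config '", file, "': entry missing field(s): ",
           paste(miss, collapse = ", "))
    ax <- if (is.null(e$allowed_axes)) c("x", "y", "z")
    else as.character(unlist(e$allowed_axes))
    ax[ax == "TRUE"] <- "y"  # bare y parses as a YAML 1.1 boolean
    helix_spec(e$name, e$sequence, e$start, e$end,
               allowed_axes = ax,
               n_term = if (is.null(e$n_term)) "extracellular" else e$n_term)
  })
  stats::setNames(specs, vapply(specs, function(s) s$name, character(1)))
}

#' Export a per-term restraint score breakdown as CSV
#'
#' @param scores A list of [total_score()] results, or a single one.
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_score_breakdown_csv <- function(scores, file) {
  if (!is.list(scores)) scores <- list(scores)
  rows <- lapply(seq_along(scores), function(i) {
    b <- attr(scores[[i]], "breakdown")
    data.frame(conformation = i, t(b), total = as.numeric(scores[[i]]))
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}
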