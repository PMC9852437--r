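# Internal helpers shared across modules.

# Session cache for fingerprints. Keys are "<method>|<radius>|<smiles>";
# values are integer vectors of on-bit indices (NULL = unparseable).
.snapfamCache <- new.env(parent = emptyenv())

#' Clear the internal fingerprint cache
#'
#' Fingerprints are memoised per (method, radius, SMILES) within a session;
#' results never depend on cache state, only timing does.
#' @return Invisibly, the number of entries removed.
#' @export
clearFingerprintCache <- function() {
  n <- length(ls(.snapfamCache))
  rm(list = ls(.snapfamCache), envir = .snapfamCache)
  invisible(n)
}

# All structure handling goes through the OpenBabel command-line tool in a
# child process: conversions are batched per call and molecules that fail
# to parse are simply absent from the output.
.obabel <- function(args) {
  exe <- Sys.which("obabel")
  if (!nzchar(exe)) {
    stop("the 'obabel' executable is required but was not found on PATH",
         call. = FALSE)
  }
  suppressWarnings(system2(exe, args, stdout = TRUE, stderr = TRUE))
}

.writeSmiFile <- function(smiles) {
  stopifnot(!is.null(names(smiles)), !anyDuplicated(names(smiles)),
            !any(grepl("[[:space:]]", names(smiles))))
  path <- tempfile(fileext = ".smi")
  writeLines(paste(smiles, names(smiles)), path)
  path
}

# Convert named SMILES to an SDFset, dropping structures that fail to parse
# (or that survive parsing but yield invalid molfiles, e.g. single atoms).
# Returns list(sdf = SDFset or NULL, ok = names kept, skipped = dropped).
.smilesToSdf <- function(smiles) {
  empty <- is.na(smiles) | !nzchar(smiles)
  smiles <- smiles[!empty]
  failed <- names(empty)[empty]
  if (!length(smiles)) return(list(sdf = NULL, ok = character(0),
                                   skipped = failed))
  smi <- .writeSmiFile(smiles)
  out <- tempfile(fileext = ".sdf")
  .obabel(c(shQuote(smi), "-osdf", "-e", "-O", shQuote(out)))
  sdf <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(out)),
                  error = function(e) NULL)
  if (is.null(sdf) || length(sdf) == 0L) {
    return(list(sdf = NULL, ok = character(0),
                skipped = c(failed, names(smiles))))
  }
  ChemmineR::cid(sdf) <- ChemmineR::sdfid(sdf)
  sdf <- sdf[suppressWarnings(ChemmineR::validSDF(sdf))]
  ok <- intersect(names(smiles), ChemmineR::sdfid(sdf))
  list(sdf = sdf, ok = ok,
       skipped = c(failed, setdiff(names(smiles), ok)))
}

# Molecular formulae for named SMILES via the formula descriptor; returns a
# named character vector covering the structures that parsed.
.obFormula <- function(smiles) {
  empty <- is.na(smiles) | !nzchar(smiles)
  smiles <- smiles[!empty]
  if (!length(smiles)) return(character(0))
  smi <- .writeSmiFile(smiles)
  out <- tempfile(fileext = ".smi")
  .obabel(c(shQuote(smi), "-osmi", "-e", "--append", "formula",
            "-O", shQuote(out)))
  lines <- tryCatch(readLines(out, warn = FALSE), error = function(e) character(0))
  if (!length(lines)) return(character(0))
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  ids <- vapply(parts, function(p) if (length(p) >= 3) p[[2L]] else NA_character_,
                character(1))
  f <- vapply(parts, function(p) if (length(p) >= 3) p[[3L]] else NA_character_,
              character(1))
  keep <- !is.na(ids) & ids %in% names(smiles)
  stats::setNames(f[keep], ids[keep])
}

# Decode one FPS hex string (byte 0 first, LSB-first within each byte) to
# 1-based on-bit indices.
.fpsHexToBits <- function(hex) {
  n <- nchar(hex)
  bytes <- strtoi(substring(hex, seq(1L, n, 2L), seq(2L, n, 2L)), 16L)
  v <- rep(bytes, each = 8L)
  msk <- rep.int(bitwShiftL(1L, 0:7), length(bytes))
  which(bitwAnd(v, msk) != 0L)
}

# Hashed fingerprints for named SMILES via the FPS output format. Returns a
# named list of on-bit index vectors (structures that failed are absent).
.obFingerprints <- function(smiles, fpName) {
  smi <- .writeSmiFile(smiles)
  out <- tempfile(fileext = ".fps")
  .obabel(c(shQuote(smi), "-ofps", paste0("-xf", fpName), "-e",
            "-O", shQuote(out)))
  lines <- tryCatch(readLines(out, warn = FALSE), error = function(e) character(0))
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) return(list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 2L)
  bits <- lapply(parts, function(p) .fpsHexToBits(p[[1L]]))
  keep <- !is.na(ids) & ids %in% names(smiles)
  stats::setNames(bits[keep], ids[keep])
}

# Signed ppm deviation of observed from theoretical.
.ppmError <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}

# Canonical unordered pair keys for edge-set comparisons.
.pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

.emptyMatches <- function() {
  data.frame(group_id = character(0), representative_mz = numeric(0),
             compound_id = character(0), name = character(0),
             formula = character(0), adduct = character(0),
             theoretical_mz = numeric(0), ppm_error = numeric(0),
             stringsAsFactors = FALSE)
}
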