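.aa123 <- function(one) {
  out <- suppressWarnings(bio3d::aa123(one))
  out[is.na(out) | !nzchar(out)] <- "UNK"
  out
}

.asPdbFile <- function(pdb) {
  # accept a path, or PDB text as a character vector / single string
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb))
    return(pdb)
  f <- tempfile(fileext = ".pdb")
  writeLines(unlist(strsplit(pdb, "\n", fixed = TRUE)), f)
  f
}

.readPdbCa <- function(pdb, chain = NULL) {
  file <- .asPdbFile(pdb)
  parsed <- tryCatch(
    bio3d::read.pdb(file, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e)
      stop("failed to parse PDB input '", file, "': ", conditionMessage(e),
           call. = FALSE))
  atoms <- parsed$atom
  atoms$chain[is.na(atoms$chain)] <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  isCa <- atoms$type == "ATOM" & atoms$elety == "CA"
  if (!any(isCa))
    stop("no CA atoms found in '", file, "'", call. = FALSE)
  if (is.null(chain)) {
    chains <- unique(atoms$chain[isCa])
    chain <- chains[1L]
    if (length(chains) > 1L)
      warning("multiple chains present (", paste(chains, collapse = ", "),
              "); using first chain '", chain, "'", call. = FALSE)
  }
  sel <- which(isCa & atoms$chain == chain)
  if (!length(sel))
    stop("no CA atoms in chain ", chain, " of '", file, "'", call. = FALSE)
  # altloc: keep the first-listed location for each residue
  key <- paste(atoms$chain[sel], atoms$resno[sel], atoms$insert[sel])
  sel <- sel[!duplicated(key)]
  if (length(sel) < 2L)
    stop("fewer than 2 CA residues in chain ", chain, " of '", file, "'",
         call. = FALSE)
  xyz <- parsed$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  resIds <- data.frame(chain = atoms$chain[sel],
                       resno = as.integer(atoms$resno[sel]),
                       insert = atoms$insert[sel], stringsAsFactors = FALSE)
  sequence <- suppressWarnings(bio3d::aa321(atoms$resid[sel]))
  sequence[is.na(sequence)] <- "X"
  cols <- bio3d::atom2xyz(sel)
  list(xyz = xyz, cols = cols, resIds = resIds, sequence = sequence)
}

#' Read a C-alpha trace from a PDB file
#'
#' Extracts one point per residue from the \code{CA} \code{ATOM} records of a
#' PDB file, in file order. \code{HETATM} records are ignored; for residues
#' with alternate locations the first-listed altloc is kept. If the file has
#' several chains and \code{chain} is not given, the first chain encountered
#' is used (with a warning).
#'
#' @param pdb path to a PDB file, or PDB text (single string or character
#'   vector of lines).
#' @param chain optional chain identifier.
#' @param model which MODEL block to read (default 1).
#' @return a [CaTrace-class].
#' @seealso [readCaFrames()] for all models, [writeMorphPdb()]
#' @export
readCaTrace <- function(pdb, chain = NULL, model = 1L) {
  p <- .readPdbCa(pdb, chain)
  if (model > nrow(p$xyz))
    stop("model ", model, " not present (file has ", nrow(p$xyz),
         " model(s))", call. = FALSE)
  coords <- matrix(p$xyz[model, p$cols], ncol = 3L, byrow = TRUE)
  CaTrace(coords, sequence = p$sequence, resIds = p$resIds)
}

#' Read every model of a multi-model PDB file as a list of C-alpha traces
#'
#' @inheritParams readCaTrace
#' @return a list of [CaTrace-class], one per MODEL block.
#' @export
readCaFrames <- function(pdb, chain = NULL) {
  p <- .readPdbCa(pdb, chain)
  lapply(seq_len(nrow(p$xyz)), function(m) {
    coords <- matrix(p$xyz[m, p$cols], ncol = 3L, byrow = TRUE)
    CaTrace(coords, sequence = p$sequence, resIds = p$resIds)
  })
}

#' Write a morph trajectory as a multi-model CA-only PDB file
#'
#' One \code{MODEL}/\code{ENDMDL} block is written per frame, containing one
#' fixed-column \code{ATOM} record per residue (CA only, coordinates to three
#' decimals, occupancy 1.00, B-factor 0.00, element C), so output is
#' bit-stable and diffable.
#'
#' @param frames a [MorphResult-class], a list of [CaTrace-class], or a
#'   single [CaTrace-class].
#' @param file optional path; when given the text is written there.
#' @return invisibly, the character vector of PDB lines.
#' @export
writeMorphPdb <- function(frames, file = NULL) {
  if (is(frames, "MorphResult")) frames <- frames@frames
  if (is(frames, "CaTrace")) frames <- list(frames)
  stopifnot(length(frames) >= 1L)
  n <- vapply(frames, nResidues, integer(1))
  if (length(unique(n)) != 1L)
    stop("all frames must have the same number of residues", call. = FALSE)
  ids <- lapply(frames, residueIds)
  if (!all(vapply(ids, identical, logical(1), ids[[1L]])))
    stop("residue identifiers differ across frames", call. = FALSE)
  rid <- ids[[1L]]
  resn <- .aa123(caSequence(frames[[1L]]))
  lines <- character(0)
  for (m in seq_along(frames)) {
    xyz <- caCoords(frames[[m]])
    atom <- sprintf(
      "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(n[1L]), resn, substr(rid$chain, 1, 1), rid$resno,
      substr(paste0(rid$insert, " "), 1, 1),
      xyz[, 1L], xyz[, 2L], xyz[, 3L], 1, 0, " C")
    lines <- c(lines, sprintf("MODEL     %4d", m), atom, "ENDMDL")
  }
  lines <- c(lines, "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
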