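## Model I/O: PDB and mmCIF, reduced to the three coarse atoms per
## residue (P, C4', glycosidic N1/N9).

glyco_atom <- function(nt) ifelse(nt %in% c("A", "G"), "N9", "N1")

normalize_resid <- function(x) {
  x <- toupper(trimws(x))
  map <- c(A = "A", C = "C", G = "G", U = "U",
           ADE = "A", CYT = "C", GUA = "G", URA = "U", URI = "U",
           RA = "A", RC = "C", RG = "G", RU = "U")
  unname(map[x])
}

#' Read a coarse-grained model from a PDB or mmCIF file
#'
#' Keeps one P, one C4' and one glycosidic nitrogen (N9 for purines, N1
#' for pyrimidines) per residue; for alternate locations the highest
#' occupancy wins. Residues with unknown names are skipped with a
#' warning; missing atoms become `NA` coordinates. Base pairs are not
#' stored in coordinate files, so the returned model has none; recover
#' them with [annotate_secondary_structure()].
#'
#' @param path `.pdb` or `.cif`/`.mmcif` file.
#' @return an `rna_model`.
#' @export
read_model <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  at <- if (ext %in% c("cif", "mmcif")) {
    read_mmcif_atoms(path)
  } else {
    bio3d::read.pdb(path, rm.alt = FALSE)$atom
  }
  nt <- normalize_resid(at$resid)
  drop <- is.na(nt)
  if (any(drop)) {
    warning("skipping ", length(unique(at$resid[drop])),
            " unknown residue name(s): ",
            paste(unique(at$resid[drop]), collapse = ", "))
  }
  at <- at[!drop, , drop = FALSE]; nt <- nt[!drop]
  if (!nrow(at)) stop("no RNA residues in ", path)
  chains <- unique(at$chain)
  if (length(chains) > 1L) {
    warning("multiple chains in ", basename(path), "; using first RNA chain '",
            chains[1], "'")
    keep <- at$chain == chains[1]
    at <- at[keep, , drop = FALSE]; nt <- nt[keep]
  }
  key <- paste(at$chain, at$resno, at$insert)
  rid <- match(key, unique(key))
  n <- max(rid)
  seq <- character(n)
  seq[rid] <- nt
  mats <- list(P = matrix(NA_real_, n, 3), C4p = matrix(NA_real_, n, 3),
               N = matrix(NA_real_, n, 3))
  occ <- list(P = rep(-Inf, n), C4p = rep(-Inf, n), N = rep(-Inf, n))
  elety <- trimws(at$elety)
  slot <- rep(NA_character_, nrow(at))
  slot[elety == "P"] <- "P"
  slot[elety %in% c("C4'", "C4*")] <- "C4p"
  slot[elety == glyco_atom(seq[rid])] <- "N"
  o <- if (is.null(at$o)) rep(1, nrow(at)) else ifelse(is.na(at$o), 1, at$o)
  for (r in which(!is.na(slot))) {
    s <- slot[r]; i <- rid[r]
    if (o[r] > occ[[s]][i]) {
      occ[[s]][i] <- o[r]
      mats[[s]][i, ] <- c(at$x[r], at$y[r], at$z[r])
    }
  }
  if (all(is.na(mats$N[, 1]))) stop("no RNA residues in ", path)
  miss <- which(is.na(mats$C4p[, 1]))
  if (length(miss)) {
    stop("residue ", seq[miss[1]], miss[1], " is missing its C4' atom")
  }
  new_model(seq, mats$P, mats$C4p, mats$N, NULL,
            provenance = setNames(basename(path), "file"))
}

## minimal generic reader for the mmCIF _atom_site loop; returns a data
## frame shaped like bio3d's $atom table (only the columns we use)
read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tag_idx <- grep("^\\s*_atom_site\\.", lines)
  if (!length(tag_idx)) stop("no _atom_site loop in ", path)
  tags <- sub("^_atom_site\\.", "", trimws(lines[tag_idx]))
  rows <- character(0)
  for (k in seq(max(tag_idx) + 1L, length(lines))) {
    ln <- trimws(lines[k])
    if (!nzchar(ln)) next
    if (ln == "#" || grepl("^(_|loop_|data_|stop_)", ln)) break
    rows <- c(rows, ln)
  }
  toks <- lapply(rows, function(ln) {
    scan(text = ln, what = "", quiet = TRUE, quote = "'\"")
  })
  toks <- toks[vapply(toks, length, 0L) == length(tags)]
  if (!length(toks)) stop("no atom rows in ", path)
  m <- do.call(rbind, toks)
  colnames(m) <- tags
  pick <- function(...) {
    for (nm in c(...)) {
      if (nm %in% tags) {
        v <- m[, nm]
        if (any(!v %in% c(".", "?"))) return(v)
      }
    }
    rep(NA_character_, nrow(m))
  }
  num <- function(v) suppressWarnings(as.numeric(v))
  occ <- num(pick("occupancy"))
  data.frame(
    elety = pick("label_atom_id", "auth_atom_id"),
    resid = pick("label_comp_id", "auth_comp_id"),
    chain = pick("auth_asym_id", "label_asym_id"),
    resno = as.integer(num(pick("auth_seq_id", "label_seq_id"))),
    insert = "",
    o = ifelse(is.na(occ), 1, occ),
    x = num(pick("Cartn_x")), y = num(pick("Cartn_y")), z = num(pick("Cartn_z")),
    stringsAsFactors = FALSE)
}

## residues involved in at least one clash (plain quadratic scan; used for
## B-factor flags on output, n is small)
clash_residues <- function(model, cutoff = 6.0) {
  n <- length(model$seq)
  excl <- new.env()
  mark <- function(i, j) assign(paste(i, j), TRUE, excl)
  if (nrow(model$pairs)) {
    for (r in seq_len(nrow(model$pairs))) mark(model$pairs[r, 1], model$pairs[r, 2])
  }
  out <- logical(n)
  for (i in seq_len(max(0L, n - 1L))) {
    if (is.na(model$N[i, 1])) next
    for (j in (i + 1L):n) {
      if (is.na(model$N[j, 1]) || j - i <= 1L) next
      if (!is.null(excl[[paste(i, j)]])) next
      if (sqrt(sum((model$N[i, ] - model$N[j, ])^2)) < cutoff) {
        out[i] <- out[j] <- TRUE
      }
    }
  }
  out
}

model_atom_table <- function(model) {
  n <- length(model$seq)
  rows <- list()
  flag <- clash_residues(model)
  serial <- 0L
  for (i in seq_len(n)) {
    nm <- c("P", "C4'", glyco_atom(model$seq[i]))
    xyz <- rbind(model$P[i, ], model$C4p[i, ], model$N[i, ])
    for (a in 1:3) {
      if (is.na(xyz[a, 1])) next
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, elety = nm[a], resid = model$seq[i], chain = "A",
        resno = i, x = xyz[a, 1], y = xyz[a, 2], z = xyz[a, 3],
        o = 1.0, b = if (flag[i]) 10.0 else 0.0,
        elesy = substr(nm[a], 1, 1))
    }
  }
  do.call(rbind, rows)
}

#' Write a coarse-grained model to PDB or mmCIF
#'
#' Three pseudo-atoms per residue on chain A. The B-factor column flags
#' residues involved in at least one steric clash (10.0, otherwise 0.0)
#' so problem regions are easy to colour in a viewer. The format follows
#' the file extension: `.cif`/`.mmcif` writes a minimal `atom_site`
#' mmCIF loop, anything else a PDB file.
#'
#' @param model an `rna_model`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_model <- function(model, path) {
  tb <- model_atom_table(model)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("cif", "mmcif")) {
    write_mmcif(tb, path)
  } else {
    bio3d::write.pdb(file = path, xyz = as.vector(t(as.matrix(tb[, c("x", "y", "z")]))),
                     type = rep("ATOM", nrow(tb)), resno = tb$resno,
                     resid = tb$resid, eleno = tb$serial, elety = tb$elety,
                     chain = tb$chain, o = tb$o, b = tb$b, elesy = tb$elesy)
  }
  invisible(path)
}

write_mmcif <- function(tb, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("data_model",
               "#",
               "loop_",
               "_atom_site.group_PDB",
               "_atom_site.id",
               "_atom_site.type_symbol",
               "_atom_site.label_atom_id",
               "_atom_site.label_comp_id",
               "_atom_site.label_asym_id",
               "_atom_site.label_seq_id",
               "_atom_site.Cartn_x",
               "_atom_site.Cartn_y",
               "_atom_site.Cartn_z",
               "_atom_site.occupancy",
               "_atom_site.B_iso_or_equiv"), con)
  quote_atom <- function(a) ifelse(grepl("'", a), paste0('"', a, '"'), a)
  writeLines(sprintf("ATOM %d %s %s %s %s %d %.3f %.3f %.3f %.2f %.2f",
                     tb$serial, tb$elesy, quote_atom(tb$elety), tb$resid,
                     tb$chain, tb$resno, tb$x, tb$y, tb$z, tb$o, tb$b), con)
  writeLines("#", con)
  invisible(path)
}
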