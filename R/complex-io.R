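#' Serialize synthetic complexes
#'
#' A complex is written as a small file set in one directory:
#' * `<id>_ligand.sdf` — the ligand (V2000, SMILES and charges as SD tags)
#' * `<id>_protein.pdb` — one HETATM pseudo-atom per synthetic residue,
#'   residue names HBA / HBD / HPH, occupancy 1.00, coordinates to 3 decimals
#' * `<id>_label.csv` — complex id, rule, label, total score, seed
#' * `<id>_contributions.csv` — per-atom ground-truth contributions
#' * `<id>_records.csv` — interaction records (residue, atom, type,
#'   distance, score)
#'
#' [read_complex()] inverts [write_complex()] up to coordinate rounding
#' (PDB: 3 decimals, SDF: 4 decimals). The PDB is read back with bio3d.
#'
#' @name complex_io
NULL

PDB_RESNAME <- c(HBA = "HBA", HBD = "HBD", Hydrophobic = "HPH")
PDB_RESNAME_INV <- c(HBA = "HBA", HBD = "HBD", HPH = "Hydrophobic")

protein_to_pdb_lines <- function(protein) {
  res <- protein$residues
  if (!nrow(res)) return("END")
  c(sprintf("HETATM%5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            seq_len(nrow(res)), "X", PDB_RESNAME[res$type], seq_len(nrow(res)),
            res$x, res$y, res$z, "X"),
    "END")
}

#' Write a complex to a directory
#'
#' @param complex An `sb_complex`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the named character vector of file paths.
#' @export
write_complex <- function(complex, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  id <- complex$id
  paths <- c(ligand = file.path(out_dir, paste0(id, "_ligand.sdf")),
             protein = file.path(out_dir, paste0(id, "_protein.pdb")),
             label = file.path(out_dir, paste0(id, "_label.csv")),
             contributions = file.path(out_dir, paste0(id, "_contributions.csv")),
             records = file.path(out_dir, paste0(id, "_records.csv")))
  write_ligands_sdf(ligand_set(list(complex$ligand)), paths[["ligand"]])
  writeLines(protein_to_pdb_lines(complex$protein), paths[["protein"]])
  write.csv(data.frame(complex_id = id, rule = complex$rule,
                       label = complex$label,
                       total_score = complex$total_score,
                       seed = complex$seed),
            paths[["label"]], row.names = FALSE)
  write.csv(data.frame(atom_idx = seq_along(complex$contributions),
                       contribution = complex$contributions),
            paths[["contributions"]], row.names = FALSE)
  write.csv(as.data.frame(complex$records), paths[["records"]], row.names = FALSE)
  invisible(paths)
}

#' Read a complex back from its file set
#'
#' @param out_dir Directory written by [write_complex()].
#' @param id Complex id (file-name prefix).
#' @param config The [generation_config()] to attach (rule is checked
#'   against the label file); defaults to the rule's default config.
#' @return An `sb_complex` re-evaluated from the stored structures.
#' @export
read_complex <- function(out_dir, id, config = NULL) {
  lab <- read.csv(file.path(out_dir, paste0(id, "_label.csv")),
                  stringsAsFactors = FALSE)
  if (is.null(config)) config <- generation_config(lab$rule)
  assert_that(identical(config$rule, lab$rule),
              "config rule does not match the stored label file")
  ligset <- load_ligands(file.path(out_dir, paste0(id, "_ligand.sdf")), "sdf")
  lig <- ligset$mol[[1]]
  lig$has_3d <- TRUE
  pdb_path <- file.path(out_dir, paste0(id, "_protein.pdb"))
  protein <- read_protein_pdb(pdb_path, make_box(lig, config$pad))
  assignment <- assign_pharmacophores(lig, config$rule)
  cx <- build_complex(lig, assignment, protein, config, lab$seed)
  cx$id <- id
  cx
}

read_protein_pdb <- function(path, box) {
  n_het <- sum(grepl("^HETATM", readLines(path, warn = FALSE)))
  if (n_het == 0) {
    return(structure(list(residues = tibble::tibble(x = numeric(0), y = numeric(0),
                                                    z = numeric(0), type = character(0)),
                          box = box, n_res_cap = NA_integer_),
                     class = "sb_protein"))
  }
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom[pdb$atom$type == "HETATM", , drop = FALSE]
  bad <- !a$resid %in% names(PDB_RESNAME_INV)
  if (any(bad)) {
    abort(sprintf("unrecognised residue name(s) in %s: %s", path,
                  paste(unique(a$resid[bad]), collapse = ", ")))
  }
  structure(list(residues = tibble::tibble(x = a$x, y = a$y, z = a$z,
                                           type = unname(PDB_RESNAME_INV[a$resid])),
                 box = box, n_res_cap = NA_integer_),
            class = "sb_protein")
}

#' Write / read a generation config as a key-value text file
#'
#' @param config A [generation_config()].
#' @param path File path.
#' @export
write_generation_config <- function(config, path) {
  writeLines(paste(names(config), vapply(config, as.character, character(1)),
                   sep = " = "), path)
  invisible(path)
}

#' @rdname write_generation_config
#' @export
read_generation_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines[nzchar(trimws(lines))], "\\s*=\\s*")
  vals <- setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, 1, FUN.VALUE = character(1)))
  num <- setdiff(names(vals), "rule")
  args <- c(list(rule = vals$rule), lapply(vals[num], as.numeric))
  do.call(generation_config, args)
}
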