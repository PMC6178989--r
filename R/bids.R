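#' Discover BIDS-organized PET acquisitions
#'
#' Walks a BIDS root (`sub-*/[ses-*/]pet/*_pet.nii[.gz]`) and returns one
#' record per PET acquisition. Entities `sub`, `ses`, `task` and `run` are
#' parsed from `key-value` filename tokens; unknown entities are preserved in
#' the filename but ignored. A matching T1-weighted image (`anat/*_T1w.nii*`)
#' and label volume (`anat/*_dseg.nii*`) are attached when present; records
#' missing a T1 are returned with `t1_path = NA` and a warning. An arterial
#' `.dft` file next to the PET image is attached when present. Results are
#' ordered lexicographically by PET path, so discovery is deterministic.
#'
#' @param root BIDS root directory.
#' @return A data frame of class `subject_records` with columns `subject_id`,
#'   `session_id`, `task_id`, `run_id`, `pet_path`, `sidecar_path`, `t1_path`,
#'   `label_path`, `dft_path` (missing entries are `NA`).
#' @export
discover_bids <- function(root) {
  assert_that(dir.exists(root), "BIDS root does not exist: %s", root)
  subs <- sort(list.dirs(root, recursive = FALSE, full.names = TRUE))
  subs <- subs[grepl("^sub-[A-Za-z0-9]+$", basename(subs))]
  assert_that(length(subs) > 0, "no sub-* directories under %s", root)
  pets <- sort(list.files(root, pattern = "_pet\\.nii(\\.gz)?$",
                          recursive = TRUE, full.names = TRUE))
  assert_that(length(pets) > 0, "no *_pet.nii[.gz] files under %s", root)
  recs <- lapply(pets, function(p) {
    ent <- parse_bids_entities(basename(p))
    assert_that(!is.na(ent["sub"]), "PET file without sub- entity: %s", p)
    # anat folder at the same subject/session level as the pet folder
    anat <- file.path(dirname(dirname(p)), "anat")
    t1 <- sort(list.files(anat, pattern = "_T1w\\.nii(\\.gz)?$",
                          full.names = TRUE))
    lab <- sort(list.files(anat, pattern = "_dseg\\.nii(\\.gz)?$",
                           full.names = TRUE))
    stem <- sub("\\.nii(\\.gz)?$", "", p)
    sidecar <- paste0(stem, ".json")
    dft <- paste0(stem, ".dft")
    if (length(t1) == 0)
      warn_pq("no T1w image found for %s", basename(p))
    data.frame(subject_id = ent[["sub"]],
               session_id = ent[["ses"]],
               task_id = ent[["task"]],
               run_id = ent[["run"]],
               pet_path = p,
               sidecar_path = if (file.exists(sidecar)) sidecar else NA_character_,
               t1_path = if (length(t1)) t1[1] else NA_character_,
               label_path = if (length(lab)) lab[1] else NA_character_,
               dft_path = if (file.exists(dft)) dft else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  class(out) <- c("subject_records", "data.frame")
  out
}

# parse key-value entity tokens from a BIDS filename
parse_bids_entities <- function(filename) {
  base <- sub("\\.nii(\\.gz)?$|\\.json$", "", filename)
  tokens <- strsplit(base, "_")[[1]]
  out <- c(sub = NA_character_, ses = NA_character_,
           task = NA_character_, run = NA_character_)
  for (tok in tokens) {
    if (!grepl("^[A-Za-z]+-", tok)) next
    key <- sub("-.*$", "", tok)
    val <- sub("^[A-Za-z]+-", "", tok)
    if (key %in% names(out)) out[key] <- val
  }
  out
}
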