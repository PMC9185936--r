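#' Canonical testcross entry identifiers
#'
#' @param lines,testers character vectors of parent identifiers.
#' @return character vector `"<line>:<tester>"` for every combination,
#'   testers varying fastest.
#' @examples testcrossEntries(c("L1", "L2"), c("T1", "T2"))
#' @export
testcrossEntries <- function(lines, testers) {
  as.vector(t(outer(lines, testers, paste, sep = ":")))
}

#' Construct a line x tester design
#'
#' @param lines,testers character, parent identifiers (>= 2 each).
#' @param checks character, check entry identifiers (default none).
#' @param testerCross identifier of the tester1 x tester2 check hybrid used
#'   as the standard-heterosis check; `NA` if absent.
#' @param replicates replications per environment.
#' @param environments named list (`infested`, `non_infested`) of
#'   environment identifiers; environments are opaque location-year labels.
#' @return an [LxTDesign-class] object.
#' @export
LxTDesign <- function(lines, testers, checks = character(),
                      testerCross = NA_character_, replicates = 2,
                      environments = list()) {
  new("LxTDesign", lines = as.character(lines),
      testers = as.character(testers), checks = as.character(checks),
      testerCross = as.character(testerCross),
      replicates = as.integer(replicates), environments = environments)
}

#' Construct trial data from plot records
#'
#' @param records data.frame with the design columns `environment`,
#'   `condition`, `replicate`, `block`, `entry`, `entry_role`, `line`,
#'   `tester` and one numeric column per trait.
#' @param design the [LxTDesign-class] of the trial.
#' @param traits names of the trait columns; defaults to every non-design
#'   column of `records`.
#' @return a validated [TrialData-class] object.
#' @export
TrialData <- function(records, design, traits = NULL) {
  if (is.null(traits)) traits <- setdiff(names(records), .DESIGN_COLS)
  records$replicate <- as.integer(records$replicate)
  for (col in c("environment", "condition", "block", "entry", "entry_role",
                "line", "tester"))
    records[[col]] <- as.character(records[[col]])
  new("TrialData", records = as.data.frame(records), design = design,
      traits = traits)
}

#' Read a trial phenotype CSV
#'
#' Expects a UTF-8 comma-separated file with a header row containing every
#' design coordinate plus at least one trait column; lines starting with `#`
#' (metadata comments written by [writeTrialCsv()]) are skipped. Empty cells
#' are the missing-value sentinel and become `NA`. Rows whose entry is not
#' part of the design are rejected.
#'
#' @param path file path.
#' @param design the [LxTDesign-class] the file must conform to.
#' @return a [TrialData-class] object.
#' @export
readTrialCsv <- function(path, design) {
  rec <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  na.strings = c("", "NA"))
  missing_cols <- setdiff(.DESIGN_COLS, names(rec))
  if (length(missing_cols))
    stop("trial CSV is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  traits <- setdiff(names(rec), .DESIGN_COLS)
  if (!length(traits)) stop("trial CSV has no trait column")
  for (tr in traits) {
    v <- rec[[tr]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(coerced))
      if (length(bad))
        stop("non-numeric value in trait '", tr, "' at data row ", bad[1])
      rec[[tr]] <- coerced
    }
  }
  known <- c(testcrossEntries(design@lines, design@testers), design@checks)
  unknown <- setdiff(unique(rec$entry), known)
  if (length(unknown))
    stop("entry not in design: ", paste(unknown, collapse = ", "))
  TrialData(rec, design, traits)
}

#' Write trial data (or any table) as CSV with a metadata header
#'
#' The first line is a `#` comment carrying the tool version and, when
#' supplied, the seed and configuration hash, so written files are
#' self-describing and reproducible reruns are byte-identical.
#'
#' @param x a [TrialData-class] object or a data.frame.
#' @param path output file path.
#' @param seed,configHash optional metadata recorded in the comment line.
#' @return `path`, invisibly.
#' @export
writeTrialCsv <- function(x, path, seed = NULL, configHash = NULL) {
  df <- if (is(x, "TrialData")) records(x) else as.data.frame(x)
  meta <- paste0("# testcross v", as.character(packageVersion("testcross")),
                 if (!is.null(seed)) paste0(" seed=", seed),
                 if (!is.null(configHash)) paste0(" config=", configHash))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Entry means over replicates (and environments)
#'
#' Arithmetic means per entry for one trait, either within each environment
#' (`per_env`) or across replicates x environments (`across_env`). Missing
#' plots are skipped and the effective n is reported; an entry with no
#' non-missing observation gets `mean = NA, n = 0`.
#'
#' @param x a [TrialData-class] object.
#' @param trait trait column name.
#' @param condition `"infested"`, `"non_infested"`, or `"across_mtl"` to
#'   pool the two research conditions (every location-year is one
#'   environment).
#' @param level `"across_env"` (default) or `"per_env"`.
#' @return data.frame with columns entry, line, tester, entry_role
#'   (plus environment when `level = "per_env"`), mean and n.
#' @examples
#' sim <- simulateTrial(trialSimConfig(nLines = 3), seed = 1)
#' head(cellMeans(sim$trial, "grain_yield", "infested"))
#' @export
cellMeans <- function(x, trait, condition = c("across_mtl", "infested",
                                              "non_infested"),
                      level = c("across_env", "per_env")) {
  condition <- match.arg(condition)
  level <- match.arg(level)
  stopifnot(trait %in% traitNames(x))
  rec <- records(x)
  if (condition != "across_mtl") rec <- rec[rec$condition == condition, ]
  if (!nrow(rec)) stop("no records for condition ", condition)
  keyCols <- c("entry", "line", "tester", "entry_role",
               if (level == "per_env") "environment")
  key <- do.call(paste, c(rec[keyCols], sep = "\r"))
  v <- rec[[trait]]
  n <- tapply(!is.na(v), key, sum)
  m <- tapply(v, key, function(z) if (all(is.na(z))) NA_real_
              else mean(z, na.rm = TRUE))
  parts <- do.call(rbind, strsplit(names(n), "\r", fixed = TRUE))
  out <- data.frame(parts, stringsAsFactors = FALSE)
  names(out) <- keyCols
  out$line[out$line == "NA"] <- NA
  out$tester[out$tester == "NA"] <- NA
  out$mean <- as.numeric(m)
  out$n <- as.integer(n)
  rownames(out) <- NULL
  out[order(out$entry), , drop = FALSE]
}

#' Testcross means as a lines x testers matrix
#'
#' @param x a [TrialData-class] object.
#' @param trait,condition as in [cellMeans()].
#' @return numeric matrix, design lines x testers, of across-environment
#'   testcross means.
#' @export
testcrossMeanMatrix <- function(x, trait, condition = "across_mtl") {
  cm <- cellMeans(x, trait, condition)
  cm <- cm[cm$entry_role == "testcross", ]
  des <- trialDesign(x)
  m <- matrix(NA_real_, length(des@lines), length(des@testers),
              dimnames = list(des@lines, des@testers))
  m[cbind(cm$line, cm$tester)] <- cm$mean
  m
}
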