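#' Write a configuration as extended XYZ
#'
#' One frame per call; `append = TRUE` accumulates a trajectory. The comment
#' line carries the orthorhombic lattice and a Properties string with
#' species, position, velocity, mass, charge, molecule id, group label and
#' leaflet id, so [read_extxyz()] reconstructs the full particle system.
#'
#' @param system a [particle_system()]
#' @param box a [sim_box()]
#' @param file path
#' @param append append a frame instead of overwriting
#' @export
write_extxyz <- function(system, box, file, append = FALSE) {
  n <- n_particles(system)
  sp <- c(WATER = "W", HEAD = "H", TAIL = "T")[system$group]
  l <- box$lengths
  hdr <- sprintf(
    'Lattice="%.8g 0 0 0 %.8g 0 0 0 %.8g" Properties=species:S:1:pos:R:3:vel:R:3:mass:R:1:charge:R:1:mol:I:1:leaflet:I:1 pbc="T T T"',
    l[1], l[2], l[3])
  lf <- ifelse(is.na(system$leaflet), -1L, system$leaflet)
  body <- sprintf("%s %.10g %.10g %.10g %.10g %.10g %.10g %.6g %.6g %d %d",
                  sp, system$positions[, 1], system$positions[, 2],
                  system$positions[, 3], system$velocities[, 1],
                  system$velocities[, 2], system$velocities[, 3],
                  system$mass, system$charge, system$mol_id, lf)
  con <- file(file, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(c(as.character(n), hdr, body), con)
  invisible(file)
}

#' Read one or more extended-XYZ frames
#'
#' @param file path written by [write_extxyz()] (or any extended XYZ with
#'   the same columns)
#' @return a list of `list(system, box)` per frame; a single frame is
#'   returned unwrapped
#' @export
read_extxyz <- function(file) {
  lines <- readLines(file)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    hdr <- lines[i + 1]
    lat <- regmatches(hdr, regexpr('Lattice="[^"]*"', hdr))
    nums <- as.numeric(strsplit(sub('Lattice="', "", sub('"$', "", lat)),
                                "\\s+")[[1]])
    body <- lines[(i + 2):(i + 1 + n)]
    m <- do.call(rbind, strsplit(trimws(body), "\\s+"))
    grp <- unname(c(W = "WATER", H = "HEAD", T = "TAIL")[m[, 1]])
    num <- apply(m[, 2:11, drop = FALSE], 2, as.numeric)
    lf <- as.integer(num[, 10])
    sys <- particle_system(num[, 1:3], num[, 4:6],
                           mass = num[, 7], charge = num[, 8],
                           type = unname(c(WATER = 1L, HEAD = 2L, TAIL = 3L)[grp]),
                           mol_id = as.integer(num[, 9]), group = grp,
                           leaflet = ifelse(lf < 0, NA_integer_, lf))
    frames[[length(frames) + 1]] <- list(system = sys,
                                         box = sim_box(nums[1], nums[5], nums[9]))
    i <- i + 2 + n
  }
  if (length(frames) == 1) frames[[1]] else frames
}

#' Write a temperature profile, ledger, curve or decomposition as TSV
#'
#' @param x a `temperature_profile`, `vt_curve`, `exchange_ledger` or
#'   `resistance_decomposition`
#' @param file path; for objects carrying a generation truth, a sidecar
#'   `<file>.truth.json` is written as well (requires jsonlite)
#' @export
write_tsv_report <- function(x, file) {
  df <- if (inherits(x, "exchange_ledger")) x$events
  else if (inherits(x, "resistance_decomposition")) {
    utils::write.table(x$segments, file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    utils::write.table(x$interfaces, sub("(\\.tsv)?$", "_interfaces.tsv", file),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(file))
  } else as.data.frame(x)
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  truth <- attr(x, "truth")
  if (!is.null(truth) && requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(truth, paste0(file, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(file)
}
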