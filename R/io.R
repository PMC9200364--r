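# Trajectory readers/writers: XYZ-style coordinates (element column =
# component tag), tab-delimited forces, CSV attachment log, per-frame
# lattice totals.  All plain text, lossless round trip.

#' Write a trajectory to a directory
#'
#' Files: `coords.xyz` (frame-stamped XYZ with the component tag as the
#' element column), `forces.tsv` (frame, bead, fx, fy, fz),
#' `attachments.csv` (frame log of Ndc80 bonds), `phospho.tsv` (per-site
#' phosphostates), `totals.tsv` (lattice species totals).
#'
#' @param traj a `spindle_trajectory`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tags <- traj$cell$state$tag
  xyz <- file(file.path(dir, "coords.xyz"), "w")
  on.exit(close(xyz))
  frc <- NULL; attl <- NULL; phl <- NULL; totl <- NULL
  for (fi in seq_along(traj$frames)) {
    fr <- traj$frames[[fi]]
    n <- nrow(fr$pos)
    writeLines(c(as.character(n),
                 sprintf("frame %d time %.6f s", fi, fr$time)), xyz)
    writeLines(sprintf("%s %.4f %.4f %.4f", tags, fr$pos[, 1], fr$pos[, 2],
                       fr$pos[, 3]), xyz)
    if (!is.null(fr$forces)) {
      frc <- rbind(frc, cbind(frame = fi, bead = seq_len(n), fr$forces))
    }
    if (nrow(fr$attach)) {
      attl <- rbind(attl, cbind(frame = fi, fr$attach))
    }
    phl <- rbind(phl, c(fi, fr$time, fr$p_sites))
    totl <- rbind(totl, c(frame = fi, time = fr$time, fr$lattice_totals))
  }
  if (!is.null(frc)) {
    colnames(frc) <- c("frame", "bead", "fx", "fy", "fz")
    write.table(frc, file.path(dir, "forces.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  if (!is.null(attl)) {
    write.table(attl, file.path(dir, "attachments.csv"), sep = ",",
                row.names = FALSE, quote = FALSE)
  } else {
    writeLines("frame,i_mt,i_site,k,l0", file.path(dir, "attachments.csv"))
  }
  write.table(phl, file.path(dir, "phospho.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (!is.null(totl)) {
    write.table(totl, file.path(dir, "totals.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read trajectory frames back from a directory
#'
#' Reconstructs the per-frame positions, forces, attachments and
#' phosphostates written by [write_trajectory()].
#'
#' @param dir directory written by [write_trajectory()].
#' @return list of frames (`time`, `pos`, `tag`, `forces`, `attach`,
#'   `p_sites`).
#' @export
read_trajectory <- function(dir) {
  lines <- readLines(file.path(dir, "coords.xyz"))
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    hdr <- strsplit(lines[i + 1], " ")[[1]]
    fidx <- as.integer(hdr[2]); ftime <- as.numeric(hdr[4])
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(block, " ", fixed = TRUE)
    tag <- vapply(parts, `[[`, character(1), 1)
    pos <- t(vapply(parts, function(pp) as.numeric(pp[2:4]), numeric(3)))
    frames[[fidx]] <- list(time = ftime, pos = pos, tag = tag)
    if (i + 1 + n > length(lines) - 1) { i <- i + 2 + n; break }
    i <- i + 2 + n
  }
  fpath <- file.path(dir, "forces.tsv")
  if (file.exists(fpath)) {
    ftab <- read.table(fpath, header = TRUE)
    for (fi in unique(ftab$frame)) {
      sub <- ftab[ftab$frame == fi, ]
      frames[[fi]]$forces <- as.matrix(sub[order(sub$bead), c("fx", "fy",
                                                              "fz")])
    }
  }
  apath <- file.path(dir, "attachments.csv")
  if (file.exists(apath)) {
    atab <- read.table(apath, header = TRUE, sep = ",")
    for (fi in seq_along(frames)) {
      sub <- atab[atab$frame == fi, -1, drop = FALSE]
      frames[[fi]]$attach <- as.matrix(sub)
    }
  }
  ppath <- file.path(dir, "phospho.tsv")
  if (file.exists(ppath)) {
    ptab <- as.matrix(read.table(ppath, sep = "\t"))
    for (r in seq_len(nrow(ptab))) {
      fi <- as.integer(ptab[r, 1])
      frames[[fi]]$p_sites <- as.integer(ptab[r, -(1:2)])
    }
  }
  frames
}
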