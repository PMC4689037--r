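#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Naive exact/one-mismatch read mapper for toy genomes.
//
// For every insert the full genome is scanned on both strands (the
// reverse complement of the insert against the forward genome), counting
// Hamming mismatches with early exit at 2.  Hits are stratified by
// mismatch count: a 0-mismatch hit beats any 1-mismatch hit; more than
// one hit in the best stratum marks the insert as a multimapper.
//
// Returns, per insert: best mismatch count (0/1, or NA if unmapped),
// number of best-stratum hits, contig index (1-based), 0-based start on
// the forward genome, and strand ("+" if the insert matched forward).

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// [[Rcpp::export]]
DataFrame naive_map_cpp(CharacterVector genome, CharacterVector inserts) {
  int nc = genome.size();
  std::vector<std::string> contigs(nc);
  for (int i = 0; i < nc; ++i) contigs[i] = as<std::string>(genome[i]);

  int n = inserts.size();
  IntegerVector best_mm(n), n_best(n), contig_idx(n), start(n);
  CharacterVector strand(n);

  for (int r = 0; r < n; ++r) {
    std::string ins = as<std::string>(inserts[r]);
    int L = ins.size();
    std::string rc(L, 'N');
    for (int i = 0; i < L; ++i) rc[L - 1 - i] = comp(ins[i]);

    int bmm = 2, hits = 0, hc = -1, hp = -1;
    char hs = '+';
    for (int s = 0; s < 2; ++s) {
      const std::string &q = (s == 0) ? ins : rc;
      char st = (s == 0) ? '+' : '-';
      for (int c = 0; c < nc; ++c) {
        const std::string &g = contigs[c];
        int glen = g.size();
        for (int p = 0; p + L <= glen; ++p) {
          int mm = 0;
          for (int i = 0; i < L; ++i) {
            if (g[p + i] != q[i] && ++mm > bmm) break;
          }
          if (mm > 1 || mm > bmm) continue;
          if (mm < bmm) { bmm = mm; hits = 0; }
          ++hits;
          hc = c; hp = p; hs = st;
        }
      }
    }
    if (bmm > 1 || hits == 0) {
      best_mm[r] = NA_INTEGER; n_best[r] = 0;
      contig_idx[r] = NA_INTEGER; start[r] = NA_INTEGER;
      strand[r] = NA_STRING;
    } else {
      best_mm[r] = bmm; n_best[r] = hits;
      contig_idx[r] = hc + 1; start[r] = hp;
      strand[r] = std::string(1, hs);
    }
  }
  return DataFrame::create(_["best_mm"] = best_mm, _["n_best"] = n_best,
                           _["contig"] = contig_idx, _["start"] = start,
                           _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}
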