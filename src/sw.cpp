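#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman, Gotoh). A gap of length k
// costs gap_open + k * gap_extend. Sequences arrive as 0-based integer
// codes into the scoring matrix; code handling (X -> zero-scoring column)
// happens on the R side when the matrix is built.

static const int NEG = INT_MIN / 4;

static int sw_score_core(const std::vector<int> &a, const std::vector<int> &b,
                         const IntegerMatrix &sm, int go, int ge) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> H(m + 1, 0), E(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int prev = 0; // H[i-1][j-1]
    int F = NEG;
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(E[j] - ge, H[j] - go - ge);
      F = std::max(F - ge, H[j - 1] - go - ge);
      int h = prev + sm(ai, b[j - 1]);
      if (E[j] > h) h = E[j];
      if (F > h) h = F;
      if (h < 0) h = 0;
      prev = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score_cpp")]]
int sw_score_cpp(IntegerVector a, IntegerVector b, IntegerMatrix sm,
                 int gap_open, int gap_extend) {
  std::vector<int> av(a.begin(), a.end()), bv(b.begin(), b.end());
  return sw_score_core(av, bv, sm, gap_open, gap_extend);
}

// Full DP with traceback; returns one optimal local alignment's statistics.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector a, IntegerVector b, IntegerMatrix sm,
                  int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  // State matrices: H (match/mismatch end), E (gap in subject dimension,
  // i.e. vertical), F (horizontal).
  std::vector<std::vector<int> > H(n + 1, std::vector<int>(m + 1, 0));
  std::vector<std::vector<int> > E(n + 1, std::vector<int>(m + 1, NEG));
  std::vector<std::vector<int> > F(n + 1, std::vector<int>(m + 1, NEG));
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E[i][j] = std::max(E[i - 1][j] - gap_extend,
                         H[i - 1][j] - gap_open - gap_extend);
      F[i][j] = std::max(F[i][j - 1] - gap_extend,
                         H[i][j - 1] - gap_open - gap_extend);
      int h = H[i - 1][j - 1] + sm(a[i - 1], b[j - 1]);
      if (E[i][j] > h) h = E[i][j];
      if (F[i][j] > h) h = F[i][j];
      if (h < 0) h = 0;
      H[i][j] = h;
      if (h > best ||
          (h == best && h > 0 && (i < bi || (i == bi && j < bj)))) {
        best = h; bi = i; bj = j;
      }
    }
  }
  if (best == 0) {
    return List::create(_["score"] = 0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["s_start"] = NA_INTEGER,
                        _["s_end"] = NA_INTEGER, _["aln_length"] = 0,
                        _["matches"] = 0, _["mismatches"] = 0,
                        _["gap_opens"] = 0, _["gaps"] = 0);
  }
  // Trace back from (bi, bj) in state H until a zero cell.
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E (vertical), 2 = F (horizontal)
  int matches = 0, mismatches = 0, gap_opens = 0, gaps = 0, aln_len = 0;
  while (true) {
    if (state == 0) {
      if (H[i][j] == 0) break;
      if (H[i][j] == E[i][j]) { state = 1; continue; }
      if (H[i][j] == F[i][j]) { state = 2; continue; }
      // diagonal
      aln_len++;
      if (a[i - 1] == b[j - 1]) matches++; else mismatches++;
      i--; j--;
      if (i == 0 || j == 0 || H[i][j] == 0) break;
    } else if (state == 1) {
      // vertical run: consumes query residues
      aln_len++; gaps++;
      bool opened = (E[i][j] == H[i - 1][j] - gap_open - gap_extend);
      bool extended = (E[i][j] == E[i - 1][j] - gap_extend);
      i--;
      if (opened || !extended) { gap_opens++; state = 0; }
      // else stay in E
      if (state == 0 && H[i][j] == 0) break;
    } else {
      aln_len++; gaps++;
      bool opened = (F[i][j] == H[i][j - 1] - gap_open - gap_extend);
      bool extended = (F[i][j] == F[i][j - 1] - gap_extend);
      j--;
      if (opened || !extended) { gap_opens++; state = 0; }
      if (state == 0 && H[i][j] == 0) break;
    }
  }
  return List::create(_["score"] = best, _["q_start"] = i + 1,
                      _["q_end"] = bi, _["s_start"] = j + 1,
                      _["s_end"] = bj, _["aln_length"] = aln_len,
                      _["matches"] = matches, _["mismatches"] = mismatches,
                      _["gap_opens"] = gap_opens, _["gaps"] = gaps);
}

// All-vs-all similarity search. Scores every unordered sequence pair once
// (the scorer is symmetric), converts to a Karlin-Altschul E-value, and for
// pairs at or below the cutoff recomputes one optimal alignment with
// traceback to fill the 12-column record; both directions are emitted.
// [[Rcpp::export(name = ".all_vs_all_cpp")]]
DataFrame all_vs_all_cpp(List seqs, IntegerVector taxon, CharacterVector ids,
                         IntegerMatrix sm, int gap_open, int gap_extend,
                         double K, double lambda, double evalue_cutoff,
                         bool within_taxon) {
  const int ns = seqs.size();
  std::vector<std::vector<int> > enc(ns);
  for (int i = 0; i < ns; ++i) {
    IntegerVector v = seqs[i];
    enc[i].assign(v.begin(), v.end());
  }
  std::vector<std::string> qid, sid;
  std::vector<double> pident, evalue, bitscore;
  std::vector<int> length_, mismatch, gapopen, qs, qe, ss, se;

  for (int i = 0; i < ns; ++i) {
    for (int j = i + 1; j < ns; ++j) {
      if (!within_taxon && taxon[i] == taxon[j]) continue;
      int s = sw_score_core(enc[i], enc[j], sm, gap_open, gap_extend);
      if (s <= 0) continue;
      double m = (double)enc[i].size(), n = (double)enc[j].size();
      double E = K * m * n * std::exp(-lambda * (double)s);
      if (E > evalue_cutoff) continue;
      IntegerVector ai(enc[i].begin(), enc[i].end());
      IntegerVector bj(enc[j].begin(), enc[j].end());
      List al = sw_align_cpp(ai, bj, sm, gap_open, gap_extend);
      int alen = al["aln_length"];
      int mm = al["mismatches"];
      int go_n = al["gap_opens"];
      int qsv = al["q_start"], qev = al["q_end"];
      int ssv = al["s_start"], sev = al["s_end"];
      int mt = al["matches"];
      double pid = 100.0 * (double)mt / (double)alen;
      pid = std::round(pid * 100.0) / 100.0;
      double bs = (lambda * (double)s - std::log(K)) / std::log(2.0);
      bs = std::round(bs * 10.0) / 10.0;
      // i as query
      qid.push_back(std::string(ids[i])); sid.push_back(std::string(ids[j]));
      pident.push_back(pid); length_.push_back(alen); mismatch.push_back(mm);
      gapopen.push_back(go_n); qs.push_back(qsv); qe.push_back(qev);
      ss.push_back(ssv); se.push_back(sev);
      evalue.push_back(E); bitscore.push_back(bs);
      // j as query (coordinates swapped)
      qid.push_back(std::string(ids[j])); sid.push_back(std::string(ids[i]));
      pident.push_back(pid); length_.push_back(alen); mismatch.push_back(mm);
      gapopen.push_back(go_n); qs.push_back(ssv); qe.push_back(sev);
      ss.push_back(qsv); se.push_back(qev);
      evalue.push_back(E); bitscore.push_back(bs);
    }
  }
  return DataFrame::create(
      _["qseqid"] = qid, _["sseqid"] = sid, _["pident"] = pident,
      _["length"] = length_, _["mismatch"] = mismatch,
      _["gapopen"] = gapopen, _["qstart"] = qs, _["qend"] = qe,
      _["sstart"] = ss, _["send"] = se, _["evalue"] = evalue,
      _["bitscore"] = bitscore, _["stringsAsFactors"] = false);
}
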