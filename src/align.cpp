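// Smith-Waterman local alignment (Gotoh affine gaps) and seeded top-hit
// search used by the translated-search stage. Scores follow the blastx
// convention: a gap of length k costs gap_open + k * gap_ext.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstring>

using namespace Rcpp;

namespace {

struct AlnResult {
  double score;
  int matches;   // identical aligned residue pairs
  int positives; // positive-scoring aligned residue pairs
  int columns;   // alignment columns, gaps included
};

// Map characters to scoring-matrix rows; unknown residues fall back to 'X'.
struct LetterMap {
  int idx[256];
  LetterMap(const std::vector<std::string>& letters) {
    int xi = 0;
    for (size_t i = 0; i < letters.size(); ++i)
      if (letters[i] == "X") xi = (int)i;
    for (int i = 0; i < 256; ++i) idx[i] = xi;
    for (size_t i = 0; i < letters.size(); ++i)
      idx[(unsigned char)letters[i][0]] = (int)i;
  }
};

const double NEG_INF = -1e30;

// Score-only local alignment, two-row DP. Returns best score (>= 0).
double sw_score(const std::string& q, const std::string& s,
                const int* mat, int n_letters, const LetterMap& lm,
                double go, double ge) {
  const int m = (int)q.size(), n = (int)s.size();
  if (m == 0 || n == 0) return 0.0;
  std::vector<double> H(n + 1, 0.0), E(n + 1, NEG_INF), F(n + 1, NEG_INF);
  double best = 0.0;
  std::vector<int> sidx(n);
  for (int j = 0; j < n; ++j) sidx[j] = lm.idx[(unsigned char)s[j]];
  for (int i = 1; i <= m; ++i) {
    double diag = 0.0;           // H[i-1][j-1]
    const int qi = lm.idx[(unsigned char)q[i - 1]];
    const int* row = mat + (size_t)qi * n_letters;
    for (int j = 1; j <= n; ++j) {
      double Ej = std::max(H[j - 1] - (go + ge), E[j - 1] - ge);
      F[j] = std::max(H[j] - (go + ge), F[j] - ge);  // H[j] still row i-1
      double h = diag + row[sidx[j - 1]];
      if (Ej > h) h = Ej;
      if (F[j] > h) h = F[j];
      if (h < 0.0) h = 0.0;
      diag = H[j];
      H[j] = h;
      E[j] = Ej;
      if (h > best) best = h;
    }
  }
  return best;
}

// Full DP with traceback; reports identity bookkeeping as well.
AlnResult sw_traceback(const std::string& q, const std::string& s,
                       const int* mat, int n_letters, const LetterMap& lm,
                       double go, double ge) {
  const int m = (int)q.size(), n = (int)s.size();
  AlnResult res = {0.0, 0, 0, 0};
  if (m == 0 || n == 0) return res;
  std::vector<double> H((m + 1) * (n + 1), 0.0);
  std::vector<double> E((m + 1) * (n + 1), NEG_INF);
  std::vector<double> F((m + 1) * (n + 1), NEG_INF);
  int bi = 0, bj = 0;
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    const int qi = lm.idx[(unsigned char)q[i - 1]];
    const int* row = mat + (size_t)qi * n_letters;
    for (int j = 1; j <= n; ++j) {
      const size_t c = (size_t)i * (n + 1) + j;
      const size_t up = c - (n + 1), left = c - 1, dg = up - 1;
      E[c] = std::max(H[left] - (go + ge), E[left] - ge);
      F[c] = std::max(H[up] - (go + ge), F[up] - ge);
      double h = H[dg] + row[lm.idx[(unsigned char)s[j - 1]]];
      if (E[c] > h) h = E[c];
      if (F[c] > h) h = F[c];
      if (h < 0.0) h = 0.0;
      H[c] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  res.score = best;
  if (best <= 0.0) return res;
  // Traceback from (bi, bj) until H == 0.
  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = E (gap in query), 2 = F (gap in subject)
  while (i > 0 && j > 0) {
    const size_t c = (size_t)i * (n + 1) + j;
    if (state == 0) {
      if (H[c] == 0.0) break;
      if (H[c] == E[c]) { state = 1; continue; }
      if (H[c] == F[c]) { state = 2; continue; }
      // diagonal
      res.columns++;
      if (q[i - 1] == s[j - 1]) res.matches++;
      if (mat[(size_t)lm.idx[(unsigned char)q[i - 1]] * n_letters +
              lm.idx[(unsigned char)s[j - 1]]] > 0) res.positives++;
      --i; --j;
    } else if (state == 1) {
      // gap in query (consumes subject)
      res.columns++;
      const size_t left = c - 1;
      if (E[c] == E[left] - ge) { --j; }
      else { --j; state = 0; }
    } else {
      res.columns++;
      const size_t up = c - (n + 1);
      if (F[c] == F[up] - ge) { --i; }
      else { --i; state = 0; }
    }
  }
  return res;
}

// Encode an amino-acid k-mer over the 26-letter A-Z alphabet; returns -1 if
// any character falls outside A-Z (e.g. '*').
long encode_kmer(const char* p, int k) {
  long code = 0;
  for (int i = 0; i < k; ++i) {
    int c = p[i] - 'A';
    if (c < 0 || c > 25) return -1;
    code = code * 26 + c;
  }
  return code;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".sw_align_cpp")]]
DataFrame sw_align_cpp(CharacterVector query, CharacterVector subject,
                       IntegerMatrix score_mat, CharacterVector letters,
                       double gap_open, double gap_ext) {
  const int n_letters = score_mat.nrow();
  std::vector<std::string> lets(letters.size());
  for (int i = 0; i < letters.size(); ++i) lets[i] = as<std::string>(letters[i]);
  LetterMap lm(lets);
  std::vector<int> mat(n_letters * n_letters);
  for (int i = 0; i < n_letters; ++i)
    for (int j = 0; j < n_letters; ++j)
      mat[(size_t)i * n_letters + j] = score_mat(i, j);
  const int n = query.size();
  NumericVector score(n), ident(n), posit(n);
  IntegerVector alen(n);
  for (int i = 0; i < n; ++i) {
    std::string q = as<std::string>(query[i]);
    std::string s = as<std::string>(subject[i % subject.size()]);
    AlnResult r = sw_traceback(q, s, mat.data(), n_letters, lm,
                               gap_open, gap_ext);
    score[i] = r.score;
    alen[i] = r.columns;
    ident[i] = r.columns > 0 ? 100.0 * r.matches / r.columns : NA_REAL;
    posit[i] = r.columns > 0 ? 100.0 * r.positives / r.columns : NA_REAL;
  }
  return DataFrame::create(_["score"] = score, _["identity"] = ident,
                           _["positives"] = posit, _["aln_len"] = alen);
}

//' @noRd
// [[Rcpp::export(name = ".top_hit_cpp")]]
List top_hit_cpp(List frames, CharacterVector ref_seqs,
                 IntegerMatrix score_mat, CharacterVector letters,
                 double gap_open, double gap_ext,
                 bool prefilter, int seed_k) {
  const int n_letters = score_mat.nrow();
  std::vector<std::string> lets(letters.size());
  for (int i = 0; i < letters.size(); ++i) lets[i] = as<std::string>(letters[i]);
  LetterMap lm(lets);
  std::vector<int> mat(n_letters * n_letters);
  for (int i = 0; i < n_letters; ++i)
    for (int j = 0; j < n_letters; ++j)
      mat[(size_t)i * n_letters + j] = score_mat(i, j);

  const int n_refs = ref_seqs.size();
  std::vector<std::string> refs(n_refs);
  for (int r = 0; r < n_refs; ++r) refs[r] = as<std::string>(ref_seqs[r]);

  // Seed index: k-mer -> refs containing it (deduplicated per ref).
  std::unordered_map<long, std::vector<int> > index;
  if (prefilter) {
    for (int r = 0; r < n_refs; ++r) {
      const std::string& s = refs[r];
      if ((int)s.size() < seed_k) continue;
      std::unordered_map<long, bool> seen;
      for (size_t p = 0; p + seed_k <= s.size(); ++p) {
        long code = encode_kmer(s.c_str() + p, seed_k);
        if (code < 0 || seen.count(code)) continue;
        seen[code] = true;
        index[code].push_back(r);
      }
    }
  }

  const int n_frames = frames.size();
  std::vector<CharacterVector> frame_vec(n_frames);
  for (int f = 0; f < n_frames; ++f) frame_vec[f] = frames[f];
  const int n_reads = n_frames ? frame_vec[0].size() : 0;

  std::vector<int> out_read, out_ref, out_frame, out_alen;
  std::vector<double> out_score, out_ident, out_pos;
  std::vector<long> stamp(n_refs, -1);
  const int frame_codes[6] = {1, 2, 3, -1, -2, -3};

  std::vector<std::string> fq(n_frames);
  std::vector<int> cand;
  for (int rd = 0; rd < n_reads; ++rd) {
    for (int f = 0; f < n_frames; ++f)
      fq[f] = as<std::string>(frame_vec[f][rd]);

    // Pass 1: best score over seeded (frame, ref) pairs (or all pairs).
    double best = 0.0;
    std::vector<std::pair<int, int> > tied;  // (ref, frame)
    for (int f = 0; f < n_frames; ++f) {
      const std::string& q = fq[f];
      cand.clear();
      if (prefilter) {
        if ((int)q.size() < seed_k) continue;
        const long tag = (long)rd * n_frames + f;
        for (size_t p = 0; p + seed_k <= q.size(); ++p) {
          long code = encode_kmer(q.c_str() + p, seed_k);
          if (code < 0) continue;
          std::unordered_map<long, std::vector<int> >::iterator it =
            index.find(code);
          if (it == index.end()) continue;
          for (size_t t = 0; t < it->second.size(); ++t) {
            int r = it->second[t];
            if (stamp[r] != tag) { stamp[r] = tag; cand.push_back(r); }
          }
        }
      } else {
        cand.resize(n_refs);
        for (int r = 0; r < n_refs; ++r) cand[r] = r;
      }
      for (size_t ci = 0; ci < cand.size(); ++ci) {
        const int r = cand[ci];
        double sc = sw_score(q, refs[r], mat.data(), n_letters, lm,
                             gap_open, gap_ext);
        if (sc > best) { best = sc; tied.clear(); }
        if (sc == best && best > 0.0) tied.push_back(std::make_pair(r, f));
      }
    }
    if (best <= 0.0 || tied.empty()) continue;

    // Pass 2: resolve ties by identity, then alignment length, then the
    // reference order supplied by the caller (lexicographic ref_id).
    int best_ref = -1, best_frame = -1, best_alen = -1;
    double best_ident = -1.0, best_pos = -1.0;
    for (size_t t = 0; t < tied.size(); ++t) {
      const int r = tied[t].first, f = tied[t].second;
      AlnResult a = sw_traceback(fq[f], refs[r], mat.data(), n_letters, lm,
                                 gap_open, gap_ext);
      double id = a.columns > 0 ? 100.0 * a.matches / a.columns : -1.0;
      bool better = false;
      if (best_ref < 0) better = true;
      else if (id > best_ident) better = true;
      else if (id == best_ident && a.columns > best_alen) better = true;
      else if (id == best_ident && a.columns == best_alen && r < best_ref)
        better = true;
      if (better) {
        best_ref = r; best_frame = f;
        best_ident = id; best_alen = a.columns;
        best_pos = a.columns > 0 ? 100.0 * a.positives / a.columns : -1.0;
      }
    }
    out_read.push_back(rd + 1);
    out_ref.push_back(best_ref + 1);
    out_frame.push_back(frame_codes[best_frame % 6]);
    out_score.push_back(best);
    out_ident.push_back(best_ident);
    out_pos.push_back(best_pos);
    out_alen.push_back(best_alen);
  }

  return List::create(_["read"] = wrap(out_read), _["ref"] = wrap(out_ref),
                      _["frame"] = wrap(out_frame),
                      _["score"] = wrap(out_score),
                      _["identity"] = wrap(out_ident),
                      _["positives"] = wrap(out_pos),
                      _["aln_len"] = wrap(out_alen));
}
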