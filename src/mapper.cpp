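#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include "seq_common.h"

using namespace Rcpp;

// ---------------------------------------------------------------------------
// k-mer index over a set of target sequences (forward strand only; queries
// are searched on both strands). k-mers containing N are never indexed.
// ---------------------------------------------------------------------------

struct KmerIndex {
    int k;
    std::vector<std::string> seqs;
    std::vector<std::string> names;
    std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> pos; // kmer -> (target, offset)
};

// [[Rcpp::export]]
SEXP cpp_index_build(CharacterVector seqs, CharacterVector names, int k) {
    if (k < 11 || k > 31) stop("seed length k must be in [11, 31]");
    KmerIndex *idx = new KmerIndex();
    idx->k = k;
    for (int t = 0; t < seqs.size(); ++t) {
        std::string s = as<std::string>(seqs[t]);
        idx->seqs.push_back(s);
        idx->names.push_back(as<std::string>(names[t]));
        int L = (int)s.size();
        if (L < k) {
            Rf_warning("target '%s' shorter than k; not indexed",
                       as<std::string>(names[t]).c_str());
            continue;
        }
        uint64_t kmer = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
        int valid = 0;
        for (int i = 0; i < L; ++i) {
            int b = base2bit(s[i]);
            if (b < 0) { valid = 0; kmer = 0; continue; }
            kmer = ((kmer << 2) | (uint64_t)b) & mask;
            if (++valid >= k)
                idx->pos[kmer].push_back({(int32_t)t, (int32_t)(i - k + 1)});
        }
    }
    XPtr<KmerIndex> p(idx, true);
    return p;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp) {
    XPtr<KmerIndex> idx(xp);
    IntegerVector lens(idx->seqs.size());
    for (size_t i = 0; i < idx->seqs.size(); ++i) lens[i] = (int)idx->seqs[i].size();
    return List::create(_["k"] = idx->k,
                        _["names"] = wrap(idx->names),
                        _["lengths"] = lens,
                        _["n_kmers"] = (double)idx->pos.size());
}

// [[Rcpp::export]]
int cpp_index_kmer_count(SEXP xp, int target) {
    // number of indexed k-mer positions for one target (testing hook)
    XPtr<KmerIndex> idx(xp);
    int n = 0;
    for (auto &kv : idx->pos)
        for (auto &pr : kv.second) if (pr.first == target) ++n;
    return n;
}

// ---------------------------------------------------------------------------
// banded glocal extension: the whole query must align, target ends are free
// within a window. match +1, mismatch -1, gap -2.
// ---------------------------------------------------------------------------

static const int NEG_INF = -1000000000;

struct GlocalResult {
    bool ok;
    int tstart, tend;       // target interval, 0-based half-open, window coords
    int score, matches, aln_len;
    std::string cigar;
};

static GlocalResult banded_glocal(const std::string &q, const std::string &t,
                                  int off, int band) {
    // off: expected window position of q[0]
    int m = (int)q.size(), n = (int)t.size();
    GlocalResult res; res.ok = false;
    if (m == 0 || n == 0) return res;
    // DP over rows 0..m, banded columns around i + off
    std::vector<std::vector<int>> S(m + 1), B(m + 1);   // score, backpointer
    std::vector<int> lo(m + 1), hi(m + 1);
    for (int i = 0; i <= m; ++i) {
        lo[i] = std::max(0, i + off - band);
        hi[i] = std::min(n, i + off + band);
        if (lo[i] > hi[i]) return res;
        S[i].assign(hi[i] - lo[i] + 1, NEG_INF);
        B[i].assign(hi[i] - lo[i] + 1, -1);
    }
    for (int j = lo[0]; j <= hi[0]; ++j) S[0][j - lo[0]] = 0;   // free target start
    for (int i = 1; i <= m; ++i) {
        for (int j = lo[i]; j <= hi[i]; ++j) {
            int best = NEG_INF, bp = -1;
            if (j - 1 >= lo[i - 1] && j - 1 <= hi[i - 1] && S[i - 1][j - 1 - lo[i - 1]] > NEG_INF) {
                int sc = S[i - 1][j - 1 - lo[i - 1]] + (bases_match(q[i - 1], t[j - 1]) ? 1 : -1);
                if (sc > best) { best = sc; bp = 0; }           // diagonal
            }
            if (j >= lo[i - 1] && j <= hi[i - 1] && S[i - 1][j - lo[i - 1]] > NEG_INF) {
                int sc = S[i - 1][j - lo[i - 1]] - 2;           // insertion in query
                if (sc > best) { best = sc; bp = 1; }
            }
            if (j - 1 >= lo[i] && S[i][j - 1 - lo[i]] > NEG_INF) {
                int sc = S[i][j - 1 - lo[i]] - 2;               // deletion from query
                if (sc > best) { best = sc; bp = 2; }
            }
            S[i][j - lo[i]] = best;
            B[i][j - lo[i]] = bp;
        }
    }
    int bestj = -1, bestsc = NEG_INF;
    for (int j = lo[m]; j <= hi[m]; ++j) {
        int sc = S[m][j - lo[m]];
        if (sc > bestsc) { bestsc = sc; bestj = j; }
    }
    if (bestj < 0 || bestsc <= NEG_INF) return res;
    // traceback
    std::string ops;
    int i = m, j = bestj, matches = 0;
    while (i > 0) {
        int bp = B[i][j - lo[i]];
        if (bp == 0) { ops.push_back('M'); if (bases_match(q[i - 1], t[j - 1])) ++matches; --i; --j; }
        else if (bp == 1) { ops.push_back('I'); --i; }
        else if (bp == 2) { ops.push_back('D'); --j; }
        else break;
    }
    std::reverse(ops.begin(), ops.end());
    // compress cigar
    std::string cig;
    for (size_t p = 0; p < ops.size();) {
        size_t r = p;
        while (r < ops.size() && ops[r] == ops[p]) ++r;
        cig += std::to_string(r - p); cig.push_back(ops[p]);
        p = r;
    }
    res.ok = true; res.tstart = j; res.tend = bestj; res.score = bestsc;
    res.matches = matches; res.aln_len = (int)ops.size(); res.cigar = cig;
    return res;
}

// ---------------------------------------------------------------------------
// seed-and-extend read mapping
// ---------------------------------------------------------------------------

struct Candidate { int target; char strand; int diag; int votes; };
struct Hit {
    int target; char strand; int tstart, tend;
    int score, matches, aln_len, qlen;
    std::string cigar;
};

static void collect_candidates(const KmerIndex &idx, const std::string &q, char strand,
                               int stride, int max_occ, std::vector<Candidate> &out) {
    int k = idx.k, m = (int)q.size();
    if (m < k) return;
    std::unordered_map<int64_t, int> votes;  // (target<<33)|(diag+2^31) packed
    uint64_t kmer = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int valid = 0;
    for (int i = 0; i < m; ++i) {
        int b = base2bit(q[i]);
        if (b < 0) { valid = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | (uint64_t)b) & mask;
        ++valid;
        int qpos = i - k + 1;
        if (valid < k || (qpos % stride) != 0) continue;
        auto it = idx.pos.find(kmer);
        if (it == idx.pos.end()) continue;
        if ((int)it->second.size() > max_occ) continue;
        for (auto &pr : it->second) {
            int64_t key = ((int64_t)pr.first << 33) | (int64_t)((int64_t)(pr.second - qpos) + (1LL << 31));
            votes[key]++;
        }
    }
    std::vector<std::pair<int64_t, int>> v(votes.begin(), votes.end());
    std::sort(v.begin(), v.end());
    // merge diagonals within 8 of each other on the same target
    size_t p = 0;
    while (p < v.size()) {
        int target = (int)(v[p].first >> 33);
        int64_t diag0 = (v[p].first & ((1LL << 33) - 1)) - (1LL << 31);
        int best_diag = (int)diag0, best_votes = v[p].second, total = v[p].second;
        size_t r = p + 1;
        int64_t prev = diag0;
        while (r < v.size() && (int)(v[r].first >> 33) == target) {
            int64_t d = (v[r].first & ((1LL << 33) - 1)) - (1LL << 31);
            if (d - prev > 8) break;
            total += v[r].second;
            if (v[r].second > best_votes) { best_votes = v[r].second; best_diag = (int)d; }
            prev = d; ++r;
        }
        out.push_back({target, strand, best_diag, total});
        p = r;
    }
}

static bool hit_better(const Hit &a, const Hit &b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.target != b.target) return a.target < b.target;
    if (a.tstart != b.tstart) return a.tstart < b.tstart;
    return a.strand < b.strand;
}

// [[Rcpp::export]]
DataFrame cpp_map_reads(SEXP xp, CharacterVector reads, double min_identity,
                        double band_frac, int max_candidates, int stride, int max_occ) {
    XPtr<KmerIndex> idx(xp);
    int n = reads.size();
    IntegerVector target(n), pos(n), ref_end(n), mapq(n), score(n), n_cand(n), aln_len(n);
    CharacterVector strand(n), cigar(n);
    NumericVector identity(n);
    LogicalVector mapped(n);

    for (int r = 0; r < n; ++r) {
        std::string fw = as<std::string>(reads[r]);
        std::string rv = revcomp(fw);
        int m = (int)fw.size();
        int band = std::max(5, (int)(band_frac * m + 0.5));
        std::vector<Candidate> cands;
        collect_candidates(*idx, fw, '+', stride, max_occ, cands);
        collect_candidates(*idx, rv, '-', stride, max_occ, cands);
        std::stable_sort(cands.begin(), cands.end(),
                         [](const Candidate &a, const Candidate &b) {
                             if (a.votes != b.votes) return a.votes > b.votes;
                             if (a.target != b.target) return a.target < b.target;
                             if (a.diag != b.diag) return a.diag < b.diag;
                             return a.strand < b.strand;
                         });
        if ((int)cands.size() > max_candidates) cands.resize(max_candidates);
        std::vector<Hit> hits;
        for (auto &c : cands) {
            const std::string &t = idx->seqs[c.target];
            const std::string &q = (c.strand == '+') ? fw : rv;
            int wstart = std::max(0, c.diag - band);
            int wend = std::min((int)t.size(), c.diag + m + band);
            if (wend - wstart < m / 2) continue;
            GlocalResult g = banded_glocal(q, t.substr(wstart, wend - wstart),
                                           c.diag - wstart, band);
            if (!g.ok) continue;
            double ident = (double)g.matches / (double)m;
            if (ident < min_identity) continue;
            Hit h;
            h.target = c.target; h.strand = c.strand;
            h.tstart = wstart + g.tstart; h.tend = wstart + g.tend;
            h.score = g.score; h.matches = g.matches; h.aln_len = g.aln_len;
            h.qlen = m; h.cigar = g.cigar;
            // drop duplicate hits at the same locus (two seed clusters, one alignment)
            bool dup = false;
            for (auto &e : hits)
                if (e.target == h.target && e.strand == h.strand &&
                    std::abs(e.tstart - h.tstart) <= band) { dup = true; break; }
            if (!dup) hits.push_back(h);
        }
        if (hits.empty()) {
            mapped[r] = false; target[r] = NA_INTEGER; pos[r] = NA_INTEGER;
            ref_end[r] = NA_INTEGER;
            strand[r] = NA_STRING; mapq[r] = NA_INTEGER; score[r] = NA_INTEGER;
            identity[r] = NA_REAL; cigar[r] = NA_STRING; aln_len[r] = NA_INTEGER;
            n_cand[r] = 0;
            continue;
        }
        std::stable_sort(hits.begin(), hits.end(), hit_better);
        const Hit &best = hits[0];
        int q;
        if (hits.size() == 1) q = 60;
        else if (hits[1].score == best.score) q = 0;
        else q = 30;
        mapped[r] = true;
        target[r] = best.target + 1;   // 1-based index into the index's targets
        pos[r] = best.tstart;          // 0-based position
        ref_end[r] = best.tend;        // 0-based half-open end on the target
        strand[r] = std::string(1, best.strand);
        mapq[r] = q;
        score[r] = best.score;
        identity[r] = (double)best.matches / (double)best.qlen;
        cigar[r] = best.cigar;
        aln_len[r] = best.aln_len;
        n_cand[r] = (int)hits.size();
    }
    return DataFrame::create(_["mapped"] = mapped, _["target"] = target,
                             _["pos"] = pos, _["ref_end"] = ref_end,
                             _["strand"] = strand,
                             _["mapq"] = mapq, _["score"] = score,
                             _["identity"] = identity, _["aln_len"] = aln_len,
                             _["cigar"] = cigar, _["n_candidates"] = n_cand,
                             _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// full Smith-Waterman local alignment with iterative masking for multiple
// hits; match +1, mismatch -1, gap -2
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_sw_local(std::string query, std::string target,
                       int min_score, int max_hits) {
    if (query.empty()) stop("empty query");
    size_t m = query.size(), n = target.size();
    if (m * n > 120000000ULL) stop("local alignment instance too large");
    std::vector<int> qs, qe, ts, te, sc, mt, al;

    std::string tgt = target;
    std::vector<signed char> B((m + 1) * (n + 1), -1);  // -1 marks a local start
    std::vector<int> prev(n + 1), cur(n + 1);
    for (int hit = 0; hit < max_hits; ++hit) {
        std::fill(B.begin(), B.end(), -1);
        std::fill(prev.begin(), prev.end(), 0);
        int bi = 0, bj = 0, bsc = 0;
        for (size_t i = 1; i <= m; ++i) {
            cur[0] = 0;
            signed char *Bi = &B[i * (n + 1)];
            for (size_t j = 1; j <= n; ++j) {
                int d = prev[j - 1] + (bases_match(query[i - 1], tgt[j - 1]) ? 1 : -1);
                int u = prev[j] - 2;
                int l = cur[j - 1] - 2;
                int best = 0; signed char bp = -1;
                if (d > best) { best = d; bp = 0; }
                if (u > best) { best = u; bp = 1; }
                if (l > best) { best = l; bp = 2; }
                cur[j] = best; Bi[j] = bp;
                if (best > bsc) { bsc = best; bi = (int)i; bj = (int)j; }
            }
            std::swap(prev, cur);
        }
        if (bsc < min_score) break;
        int i = bi, j = bj, matches = 0, alen = 0;
        while (i > 0 && j > 0 && B[i * (n + 1) + j] >= 0) {
            signed char bp = B[i * (n + 1) + j];
            ++alen;
            if (bp == 0) { if (bases_match(query[i - 1], tgt[j - 1])) ++matches; --i; --j; }
            else if (bp == 1) --i;
            else --j;
        }
        qs.push_back(i); qe.push_back(bi);
        ts.push_back(j); te.push_back(bj);
        sc.push_back(bsc); mt.push_back(matches); al.push_back(alen);
        for (int p = j; p < bj; ++p) tgt[p] = '#';   // mask; matches nothing
    }
    int h = (int)qs.size();
    NumericVector identity(h), coverage(h);
    for (int i = 0; i < h; ++i) {
        identity[i] = al[i] > 0 ? (double)mt[i] / (double)al[i] : 0.0;
        coverage[i] = (double)(qe[i] - qs[i]) / (double)m;
    }
    return DataFrame::create(_["qstart"] = wrap(qs), _["qend"] = wrap(qe),
                             _["tstart"] = wrap(ts), _["tend"] = wrap(te),
                             _["score"] = wrap(sc), _["matches"] = wrap(mt),
                             _["aln_len"] = wrap(al),
                             _["identity"] = identity, _["coverage"] = coverage,
                             _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
    CharacterVector out(x.size());
    for (int i = 0; i < x.size(); ++i)
        out[i] = revcomp(as<std::string>(x[i]));
    out.names() = x.names();
    return out;
}
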