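#ifndef CURVACTIN_IPQ_H
#define CURVACTIN_IPQ_H

#include <vector>
#include <limits>

// Indexed priority queue over tentative firing times: binary min-heap with a
// position index so any channel's key can be updated in O(log n).
class IndexedPriorityQueue {
public:
  explicit IndexedPriorityQueue(int n = 0) { init(n); }

  void init(int n) {
    n_ = n;
    key_.assign(n, std::numeric_limits<double>::infinity());
    heap_.resize(n);
    pos_.resize(n);
    for (int i = 0; i < n; ++i) { heap_[i] = i; pos_[i] = i; }
  }

  double key(int id) const { return key_[id]; }
  int size() const { return n_; }

  int top() const { return heap_.empty() ? -1 : heap_[0]; }
  double top_key() const {
    return heap_.empty() ? std::numeric_limits<double>::infinity()
                         : key_[heap_[0]];
  }

  void update(int id, double k) {
    double old = key_[id];
    key_[id] = k;
    if (k < old) sift_up(pos_[id]); else sift_down(pos_[id]);
  }

private:
  int n_ = 0;
  std::vector<double> key_;
  std::vector<int> heap_;  // heap slot -> id
  std::vector<int> pos_;   // id -> heap slot

  void swap_slots(int a, int b) {
    std::swap(heap_[a], heap_[b]);
    pos_[heap_[a]] = a;
    pos_[heap_[b]] = b;
  }
  void sift_up(int s) {
    while (s > 0) {
      int parent = (s - 1) / 2;
      if (key_[heap_[s]] < key_[heap_[parent]]) { swap_slots(s, parent); s = parent; }
      else break;
    }
  }
  void sift_down(int s) {
    for (;;) {
      int l = 2 * s + 1, r = l + 1, m = s;
      if (l < n_ && key_[heap_[l]] < key_[heap_[m]]) m = l;
      if (r < n_ && key_[heap_[r]] < key_[heap_[m]]) m = r;
      if (m == s) break;
      swap_slots(s, m);
      s = m;
    }
  }
};

#endif
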