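// Minimal HDF5 reader/writer for the epoch archive, built directly on the
// libhdf5 C API (no R HDF5 binding is required at runtime). The layout is a
// single file with:
//   /data    float32, dims (n_trials, n_channels, n_samples), C order
//   /labels  int32,   dims (n_trials)
// and root attributes fs (double), channel_names / class_names (variable
// length UTF-8 string arrays) and an optional subject_id scalar string.
// The C-order layout makes the file read naturally from h5py/MATLAB.

#include <Rcpp.h>
#include <hdf5.h>
#include <vector>
#include <string>
#include <cstring>

namespace {

struct HidCloser {
  std::vector<std::pair<hid_t, herr_t (*)(hid_t)>> open;
  void add(hid_t h, herr_t (*fn)(hid_t)) { if (h >= 0) open.emplace_back(h, fn); }
  ~HidCloser() {
    for (auto it = open.rbegin(); it != open.rend(); ++it) it->second(it->first);
  }
};

void write_string_attr_array(hid_t loc, const char* name,
                             const std::vector<std::string>& vals) {
  hid_t st = H5Tcopy(H5T_C_S1);
  H5Tset_size(st, H5T_VARIABLE);
  H5Tset_cset(st, H5T_CSET_UTF8);
  hsize_t n = vals.size();
  hid_t sp = H5Screate_simple(1, &n, nullptr);
  hid_t at = H5Acreate2(loc, name, st, sp, H5P_DEFAULT, H5P_DEFAULT);
  std::vector<const char*> ptrs(vals.size());
  for (size_t i = 0; i < vals.size(); ++i) ptrs[i] = vals[i].c_str();
  herr_t status = H5Awrite(at, st, ptrs.data());
  H5Aclose(at); H5Sclose(sp); H5Tclose(st);
  if (status < 0) Rcpp::stop("failed writing attribute '%s'", name);
}

void write_string_attr_scalar(hid_t loc, const char* name, const std::string& val) {
  hid_t st = H5Tcopy(H5T_C_S1);
  H5Tset_size(st, H5T_VARIABLE);
  H5Tset_cset(st, H5T_CSET_UTF8);
  hid_t sp = H5Screate(H5S_SCALAR);
  hid_t at = H5Acreate2(loc, name, st, sp, H5P_DEFAULT, H5P_DEFAULT);
  const char* p = val.c_str();
  herr_t status = H5Awrite(at, st, &p);
  H5Aclose(at); H5Sclose(sp); H5Tclose(st);
  if (status < 0) Rcpp::stop("failed writing attribute '%s'", name);
}

std::vector<std::string> read_string_attr_array(hid_t loc, const char* name) {
  if (H5Aexists(loc, name) <= 0)
    Rcpp::stop("epoch archive is missing required attribute '%s'", name);
  hid_t at = H5Aopen(loc, name, H5P_DEFAULT);
  hid_t sp = H5Aget_space(at);
  hsize_t n = 0;
  H5Sget_simple_extent_dims(sp, &n, nullptr);
  hid_t st = H5Tcopy(H5T_C_S1);
  H5Tset_size(st, H5T_VARIABLE);
  H5Tset_cset(st, H5T_CSET_UTF8);
  std::vector<char*> buf(n, nullptr);
  herr_t status = H5Aread(at, st, buf.data());
  std::vector<std::string> out;
  if (status >= 0)
    for (hsize_t i = 0; i < n; ++i) out.push_back(buf[i] ? buf[i] : "");
  H5Dvlen_reclaim(st, sp, H5P_DEFAULT, buf.data());
  H5Tclose(st); H5Sclose(sp); H5Aclose(at);
  if (status < 0) Rcpp::stop("failed reading attribute '%s'", name);
  return out;
}

}  // namespace

// [[Rcpp::export]]
void cpp_h5_write_epochs(std::string path, Rcpp::NumericVector data,
                         Rcpp::IntegerVector labels, double fs,
                         Rcpp::CharacterVector channel_names,
                         Rcpp::CharacterVector class_names,
                         Rcpp::Nullable<Rcpp::String> subject_id) {
  H5Eset_auto2(H5E_DEFAULT, nullptr, nullptr);
  Rcpp::IntegerVector dims = data.attr("dim");
  const hsize_t n = dims[0], C = dims[1], T = dims[2];

  // suppress object-header timestamps so identical content gives
  // byte-identical files (seeded simulations must reproduce exactly)
  hid_t fcpl = H5Pcreate(H5P_FILE_CREATE);
  H5Pset_obj_track_times(fcpl, 0);
  hid_t file = H5Fcreate(path.c_str(), H5F_ACC_TRUNC, fcpl, H5P_DEFAULT);
  H5Pclose(fcpl);
  if (file < 0) Rcpp::stop("cannot create HDF5 file '%s'", path);
  HidCloser guard;
  guard.add(file, H5Fclose);
  hid_t dcpl = H5Pcreate(H5P_DATASET_CREATE);
  H5Pset_obj_track_times(dcpl, 0);
  guard.add(dcpl, H5Pclose);

  // R column-major (trial fastest) -> C-order (sample fastest) float buffer
  std::vector<float> buf((size_t)n * C * T);
  const double* src = data.begin();
  for (hsize_t i = 0; i < n; ++i)
    for (hsize_t c = 0; c < C; ++c)
      for (hsize_t t = 0; t < T; ++t)
        buf[(i * C + c) * T + t] = (float)src[i + n * c + n * C * t];

  hsize_t ddims[3] = {n, C, T};
  hid_t dsp = H5Screate_simple(3, ddims, nullptr);
  hid_t dset = H5Dcreate2(file, "data", H5T_IEEE_F32LE, dsp,
                          H5P_DEFAULT, dcpl, H5P_DEFAULT);
  if (dset < 0) Rcpp::stop("cannot create dataset 'data'");
  herr_t status = H5Dwrite(dset, H5T_NATIVE_FLOAT, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                           buf.data());
  H5Dclose(dset); H5Sclose(dsp);
  if (status < 0) Rcpp::stop("failed writing dataset 'data'");

  hsize_t ldims[1] = {n};
  hid_t lsp = H5Screate_simple(1, ldims, nullptr);
  hid_t lset = H5Dcreate2(file, "labels", H5T_STD_I32LE, lsp,
                          H5P_DEFAULT, dcpl, H5P_DEFAULT);
  status = H5Dwrite(lset, H5T_NATIVE_INT, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                    labels.begin());
  H5Dclose(lset); H5Sclose(lsp);
  if (status < 0) Rcpp::stop("failed writing dataset 'labels'");

  hid_t asp = H5Screate(H5S_SCALAR);
  hid_t at = H5Acreate2(file, "fs", H5T_IEEE_F64LE, asp, H5P_DEFAULT, H5P_DEFAULT);
  status = H5Awrite(at, H5T_NATIVE_DOUBLE, &fs);
  H5Aclose(at); H5Sclose(asp);
  if (status < 0) Rcpp::stop("failed writing attribute 'fs'");

  std::vector<std::string> chn, cln;
  for (auto s : channel_names) chn.push_back(Rcpp::as<std::string>(s));
  for (auto s : class_names) cln.push_back(Rcpp::as<std::string>(s));
  write_string_attr_array(file, "channel_names", chn);
  write_string_attr_array(file, "class_names", cln);
  if (subject_id.isNotNull())
    write_string_attr_scalar(file, "subject_id",
                             Rcpp::as<std::string>(subject_id.get()));
}

// reader for the temporary file produced by the python/MNE GDF bridge:
// /signal (channels x samples, float64, C order), /ev_sample, /ev_code,
// attrs fs, ch_names, ch_types
// [[Rcpp::export]]
Rcpp::List cpp_h5_read_gdf_bridge(std::string path) {
  H5Eset_auto2(H5E_DEFAULT, nullptr, nullptr);
  hid_t file = H5Fopen(path.c_str(), H5F_ACC_RDONLY, H5P_DEFAULT);
  if (file < 0) Rcpp::stop("'%s' is not a readable HDF5 file", path);
  HidCloser guard;
  guard.add(file, H5Fclose);

  hid_t dset = H5Dopen2(file, "signal", H5P_DEFAULT);
  if (dset < 0) Rcpp::stop("bridge file is missing dataset 'signal'");
  hid_t dsp = H5Dget_space(dset);
  hsize_t sdims[2];
  H5Sget_simple_extent_dims(dsp, sdims, nullptr);
  const hsize_t C = sdims[0], S = sdims[1];
  std::vector<double> buf((size_t)C * S);
  herr_t status = H5Dread(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                          buf.data());
  H5Sclose(dsp); H5Dclose(dset);
  if (status < 0) Rcpp::stop("failed reading dataset 'signal'");
  Rcpp::NumericMatrix sig((int)C, (int)S);
  for (hsize_t c = 0; c < C; ++c)
    for (hsize_t s = 0; s < S; ++s)
      sig((int)c, (int)s) = buf[c * S + s];

  hid_t eset = H5Dopen2(file, "ev_sample", H5P_DEFAULT);
  hid_t esp = H5Dget_space(eset);
  hsize_t ne = 0;
  H5Sget_simple_extent_dims(esp, &ne, nullptr);
  std::vector<double> ev((size_t)ne);
  H5Dread(eset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, ev.data());
  H5Sclose(esp); H5Dclose(eset);

  // ev_code stored as variable-length strings
  std::vector<std::string> codes;
  {
    hid_t cset = H5Dopen2(file, "ev_code", H5P_DEFAULT);
    hid_t csp = H5Dget_space(cset);
    hsize_t nc = 0;
    H5Sget_simple_extent_dims(csp, &nc, nullptr);
    hid_t st = H5Tcopy(H5T_C_S1);
    H5Tset_size(st, H5T_VARIABLE);
    H5Tset_cset(st, H5T_CSET_UTF8);
    std::vector<char*> cbuf(nc, nullptr);
    if (H5Dread(cset, st, H5S_ALL, H5S_ALL, H5P_DEFAULT, cbuf.data()) >= 0)
      for (hsize_t i = 0; i < nc; ++i) codes.push_back(cbuf[i] ? cbuf[i] : "");
    H5Dvlen_reclaim(st, csp, H5P_DEFAULT, cbuf.data());
    H5Tclose(st); H5Sclose(csp); H5Dclose(cset);
  }

  double fs = 0;
  hid_t at = H5Aopen(file, "fs", H5P_DEFAULT);
  H5Aread(at, H5T_NATIVE_DOUBLE, &fs);
  H5Aclose(at);
  std::vector<std::string> chn = read_string_attr_array(file, "ch_names");
  std::vector<std::string> cht = read_string_attr_array(file, "ch_types");

  Rcpp::NumericVector times((R_xlen_t)ne);
  for (hsize_t i = 0; i < ne; ++i) times[(R_xlen_t)i] = ev[i] / fs;
  return Rcpp::List::create(
    Rcpp::Named("signal") = sig,
    Rcpp::Named("fs") = fs,
    Rcpp::Named("channel_names") = Rcpp::wrap(chn),
    Rcpp::Named("channel_types") = Rcpp::wrap(cht),
    Rcpp::Named("events") = Rcpp::DataFrame::create(
      Rcpp::Named("time") = times,
      Rcpp::Named("code") = Rcpp::wrap(codes),
      Rcpp::Named("stringsAsFactors") = false));
}

// [[Rcpp::export]]
Rcpp::List cpp_h5_read_epochs(std::string path) {
  H5Eset_auto2(H5E_DEFAULT, nullptr, nullptr);
  hid_t file = H5Fopen(path.c_str(), H5F_ACC_RDONLY, H5P_DEFAULT);
  if (file < 0) Rcpp::stop("'%s' is not a readable HDF5 file", path);
  HidCloser guard;
  guard.add(file, H5Fclose);

  for (const char* nm : {"data", "labels"})
    if (H5Lexists(file, nm, H5P_DEFAULT) <= 0)
      Rcpp::stop("epoch archive is missing required dataset '%s'", nm);

  hid_t dset = H5Dopen2(file, "data", H5P_DEFAULT);
  hid_t dsp = H5Dget_space(dset);
  if (H5Sget_simple_extent_ndims(dsp) != 3) {
    H5Sclose(dsp); H5Dclose(dset);
    Rcpp::stop("dataset 'data' must be 3-dimensional (trials x channels x samples)");
  }
  hsize_t ddims[3];
  H5Sget_simple_extent_dims(dsp, ddims, nullptr);
  const hsize_t n = ddims[0], C = ddims[1], T = ddims[2];
  std::vector<float> buf((size_t)n * C * T);
  herr_t status = H5Dread(dset, H5T_NATIVE_FLOAT, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                          buf.data());
  H5Sclose(dsp); H5Dclose(dset);
  if (status < 0) Rcpp::stop("failed reading dataset 'data'");

  Rcpp::NumericVector data(Rcpp::no_init((R_xlen_t)(n * C * T)));
  data.attr("dim") = Rcpp::IntegerVector::create((int)n, (int)C, (int)T);
  for (hsize_t i = 0; i < n; ++i)
    for (hsize_t c = 0; c < C; ++c)
      for (hsize_t t = 0; t < T; ++t)
        data[i + n * c + n * C * t] = (double)buf[(i * C + c) * T + t];

  hid_t lset = H5Dopen2(file, "labels", H5P_DEFAULT);
  hid_t lsp = H5Dget_space(lset);
  hsize_t ln = 0;
  H5Sget_simple_extent_dims(lsp, &ln, nullptr);
  Rcpp::IntegerVector labels((R_xlen_t)ln);
  status = H5Dread(lset, H5T_NATIVE_INT, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                   labels.begin());
  H5Sclose(lsp); H5Dclose(lset);
  if (status < 0) Rcpp::stop("failed reading dataset 'labels'");

  if (H5Aexists(file, "fs") <= 0)
    Rcpp::stop("epoch archive is missing required attribute 'fs'");
  double fs = 0;
  hid_t at = H5Aopen(file, "fs", H5P_DEFAULT);
  status = H5Aread(at, H5T_NATIVE_DOUBLE, &fs);
  H5Aclose(at);
  if (status < 0) Rcpp::stop("failed reading attribute 'fs'");

  std::vector<std::string> chn = read_string_attr_array(file, "channel_names");
  std::vector<std::string> cln = read_string_attr_array(file, "class_names");

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("data") = data,
    Rcpp::Named("labels") = labels,
    Rcpp::Named("fs") = fs,
    Rcpp::Named("channel_names") = Rcpp::wrap(chn),
    Rcpp::Named("class_names") = Rcpp::wrap(cln),
    Rcpp::Named("subject_id") = R_NilValue);
  if (H5Aexists(file, "subject_id") > 0) {
    hid_t sat = H5Aopen(file, "subject_id", H5P_DEFAULT);
    hid_t st = H5Tcopy(H5T_C_S1);
    H5Tset_size(st, H5T_VARIABLE);
    H5Tset_cset(st, H5T_CSET_UTF8);
    char* p = nullptr;
    if (H5Aread(sat, st, &p) >= 0 && p) {
      out["subject_id"] = std::string(p);
      H5free_memory(p);
    }
    H5Tclose(st); H5Aclose(sat);
  }
  return out;
}
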