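// Minimal HDF5 container support: flat files with root-level datasets and
// root-group attributes. Complex data are stored as the {r,i} float32
// compound type so that h5py reads them natively as complex64.
//
// All dims arguments are in C order (slowest-varying first); the R wrappers
// take care of permuting column-major arrays.
#include <Rcpp.h>
#include <hdf5.h>
#include <string>
#include <vector>
using namespace Rcpp;

namespace {

struct cplx32 { float r, i; };

hid_t cplx_type() {
  hid_t t = H5Tcreate(H5T_COMPOUND, sizeof(cplx32));
  H5Tinsert(t, "r", HOFFSET(cplx32, r), H5T_NATIVE_FLOAT);
  H5Tinsert(t, "i", HOFFSET(cplx32, i), H5T_NATIVE_FLOAT);
  return t;
}

hid_t open_rw(const std::string& path, bool create) {
  hid_t f = create ? H5Fcreate(path.c_str(), H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT)
                   : H5Fopen(path.c_str(), H5F_ACC_RDWR, H5P_DEFAULT);
  if (f < 0) stop("cannot open HDF5 file '%s'", path.c_str());
  return f;
}

hid_t open_ro(const std::string& path) {
  hid_t f = H5Fopen(path.c_str(), H5F_ACC_RDONLY, H5P_DEFAULT);
  if (f < 0) stop("cannot open HDF5 file '%s'", path.c_str());
  return f;
}

std::vector<hsize_t> to_hdims(IntegerVector dims) {
  std::vector<hsize_t> h(dims.size());
  for (int i = 0; i < dims.size(); ++i) h[i] = (hsize_t)dims[i];
  return h;
}

} // namespace

// [[Rcpp::export(name = ".h5_create")]]
void h5_create(std::string path) { H5Fclose(open_rw(path, true)); }

// [[Rcpp::export(name = ".h5_write_cplx")]]
void h5_write_cplx(std::string path, std::string name,
                   NumericVector re, NumericVector im, IntegerVector dims) {
  std::vector<cplx32> buf(re.size());
  for (R_xlen_t i = 0; i < re.size(); ++i) {
    buf[i].r = (float)re[i];
    buf[i].i = (float)im[i];
  }
  hid_t f = open_rw(path, false);
  std::vector<hsize_t> h = to_hdims(dims);
  hid_t sp = H5Screate_simple((int)h.size(), h.data(), NULL);
  hid_t ty = cplx_type();
  hid_t ds = H5Dcreate2(f, name.c_str(), ty, sp, H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
  if (ds < 0) { H5Tclose(ty); H5Sclose(sp); H5Fclose(f); stop("cannot create dataset '%s'", name.c_str()); }
  H5Dwrite(ds, ty, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf.data());
  H5Dclose(ds); H5Tclose(ty); H5Sclose(sp); H5Fclose(f);
}

// [[Rcpp::export(name = ".h5_write_num")]]
void h5_write_num(std::string path, std::string name, NumericVector x,
                  IntegerVector dims, std::string dtype) {
  hid_t f = open_rw(path, false);
  std::vector<hsize_t> h = to_hdims(dims);
  hid_t sp = H5Screate_simple((int)h.size(), h.data(), NULL);
  hid_t ft;
  if (dtype == "uint8") ft = H5T_NATIVE_UCHAR;
  else if (dtype == "int16") ft = H5T_NATIVE_SHORT;
  else if (dtype == "int32") ft = H5T_NATIVE_INT;
  else if (dtype == "float64") ft = H5T_NATIVE_DOUBLE;
  else ft = H5T_NATIVE_FLOAT;
  hid_t ds = H5Dcreate2(f, name.c_str(), ft, sp, H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
  if (ds < 0) { H5Sclose(sp); H5Fclose(f); stop("cannot create dataset '%s'", name.c_str()); }
  H5Dwrite(ds, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, REAL(x));
  H5Dclose(ds); H5Sclose(sp); H5Fclose(f);
}

// [[Rcpp::export(name = ".h5_read")]]
List h5_read(std::string path, std::string name) {
  hid_t f = open_ro(path);
  hid_t ds = H5Dopen2(f, name.c_str(), H5P_DEFAULT);
  if (ds < 0) { H5Fclose(f); stop("no dataset '%s'", name.c_str()); }
  hid_t sp = H5Dget_space(ds);
  const int nd = H5Sget_simple_extent_ndims(sp);
  std::vector<hsize_t> h(nd);
  H5Sget_simple_extent_dims(sp, h.data(), NULL);
  R_xlen_t n = 1;
  IntegerVector dims(nd);
  for (int i = 0; i < nd; ++i) { dims[i] = (int)h[i]; n *= (R_xlen_t)h[i]; }
  hid_t ty = H5Dget_type(ds);
  List out;
  if (H5Tget_class(ty) == H5T_COMPOUND) {
    std::vector<cplx32> buf(n);
    hid_t mt = cplx_type();
    H5Dread(ds, mt, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf.data());
    H5Tclose(mt);
    NumericVector re(n), im(n);
    for (R_xlen_t i = 0; i < n; ++i) { re[i] = buf[i].r; im[i] = buf[i].i; }
    out = List::create(_["kind"] = "complex", _["re"] = re, _["im"] = im, _["dims"] = dims);
  } else {
    NumericVector x(n);
    H5Dread(ds, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, REAL(x));
    out = List::create(_["kind"] = "numeric", _["data"] = x, _["dims"] = dims);
  }
  H5Tclose(ty); H5Sclose(sp); H5Dclose(ds); H5Fclose(f);
  return out;
}

// [[Rcpp::export(name = ".h5_ls")]]
CharacterVector h5_ls(std::string path) {
  hid_t f = open_ro(path);
  hid_t g = H5Gopen2(f, "/", H5P_DEFAULT);
  H5G_info_t info;
  H5Gget_info(g, &info);
  CharacterVector out(info.nlinks);
  for (hsize_t i = 0; i < info.nlinks; ++i) {
    char buf[512];
    H5Lget_name_by_idx(g, ".", H5_INDEX_NAME, H5_ITER_NATIVE, i, buf, sizeof(buf), H5P_DEFAULT);
    out[i] = buf;
  }
  H5Gclose(g); H5Fclose(f);
  return out;
}

// [[Rcpp::export(name = ".h5_attr_write_num")]]
void h5_attr_write_num(std::string path, std::string name, NumericVector x) {
  hid_t f = open_rw(path, false);
  hsize_t n = (hsize_t)x.size();
  hid_t sp = H5Screate_simple(1, &n, NULL);
  hid_t a = H5Acreate2(f, name.c_str(), H5T_NATIVE_DOUBLE, sp, H5P_DEFAULT, H5P_DEFAULT);
  H5Awrite(a, H5T_NATIVE_DOUBLE, REAL(x));
  H5Aclose(a); H5Sclose(sp); H5Fclose(f);
}

// [[Rcpp::export(name = ".h5_attr_write_str")]]
void h5_attr_write_str(std::string path, std::string name, std::string value) {
  hid_t f = open_rw(path, false);
  hid_t ty = H5Tcopy(H5T_C_S1);
  H5Tset_size(ty, value.size() + 1);
  hid_t sp = H5Screate(H5S_SCALAR);
  hid_t a = H5Acreate2(f, name.c_str(), ty, sp, H5P_DEFAULT, H5P_DEFAULT);
  H5Awrite(a, ty, value.c_str());
  H5Aclose(a); H5Sclose(sp); H5Tclose(ty); H5Fclose(f);
}

// [[Rcpp::export(name = ".h5_attr_list")]]
CharacterVector h5_attr_list(std::string path) {
  hid_t f = open_ro(path);
  H5O_info_t info;
#if H5_VERSION_GE(1, 12, 0)
  H5Oget_info3(f, &info, H5O_INFO_NUM_ATTRS);
#else
  H5Oget_info(f, &info);
#endif
  CharacterVector out(info.num_attrs);
  for (hsize_t i = 0; i < info.num_attrs; ++i) {
    char buf[512];
    H5Aget_name_by_idx(f, ".", H5_INDEX_NAME, H5_ITER_NATIVE, i, buf, sizeof(buf), H5P_DEFAULT);
    out[i] = buf;
  }
  H5Fclose(f);
  return out;
}

// [[Rcpp::export(name = ".h5_attr_read")]]
SEXP h5_attr_read(std::string path, std::string name) {
  hid_t f = open_ro(path);
  hid_t a = H5Aopen(f, name.c_str(), H5P_DEFAULT);
  if (a < 0) { H5Fclose(f); stop("no attribute '%s'", name.c_str()); }
  hid_t ty = H5Aget_type(a);
  SEXP out;
  if (H5Tget_class(ty) == H5T_STRING) {
    size_t sz = H5Tget_size(ty);
    std::vector<char> buf(sz + 1, 0);
    hid_t mt = H5Tcopy(H5T_C_S1);
    H5Tset_size(mt, sz + 1);
    H5Aread(a, ty, buf.data());
    H5Tclose(mt);
    out = wrap(std::string(buf.data()));
  } else {
    hid_t sp = H5Aget_space(a);
    hssize_t n = H5Sget_simple_extent_npoints(sp);
    NumericVector x(n);
    H5Aread(a, H5T_NATIVE_DOUBLE, REAL(x));
    H5Sclose(sp);
    out = x;
  }
  H5Tclose(ty); H5Aclose(a); H5Fclose(f);
  return out;
}
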