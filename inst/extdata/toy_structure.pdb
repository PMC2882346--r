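ATOM      1  CA  ALA A 301      50.500   0.000   0.000  1.00  0.00           C
ATOM      2  CA  ARG A 302      49.936   0.496   0.300  1.00  0.00           C
ATOM      3  CA  ASN A 303      49.517  -0.128   0.600  1.00  0.00           C
ATOM      4  CA  ASP A 304      50.189  -0.463   0.900  1.00  0.00           C
ATOM      5  CA  CYS A 305      50.435   0.247   1.200  1.00  0.00           C
ATOM      6  CA  GLN A 306      49.699   0.399   1.500  1.00  0.00           C
ATOM      7  CA  GLU A 307      49.643  -0.350   1.800  1.00  0.00           C
ATOM      8  CA  GLY A 308      50.393  -0.309   2.100  1.00  0.00           C
ATOM      9  CA  HIS A 309      50.256   0.430   2.400  1.00  0.00           C
ATOM     10  CA  ILE A 310      49.541   0.198   2.700  1.00  0.00           C
ATOM     11  CA  LEU A 311      31.674  39.092   0.000  1.00  0.00           C
ATOM     12  CA  LYS A 312      31.110  39.587   0.300  1.00  0.00           C
ATOM     13  CA  MET A 313      30.691  38.964   0.600  1.00  0.00           C
ATOM     14  CA  PHE A 314      31.363  38.629   0.900  1.00  0.00           C
ATOM     15  CA  PRO A 315      31.609  39.339   1.200  1.00  0.00           C
ATOM     16  CA  SER A 316      30.873  39.491   1.500  1.00  0.00           C
ATOM     17  CA  THR A 317      30.817  38.742   1.800  1.00  0.00           C
ATOM     18  CA  TRP A 318      31.568  38.783   2.100  1.00  0.00           C
ATOM     19  CA  TYR A 319      31.430  39.521   2.400  1.00  0.00           C
ATOM     20  CA  VAL A 320      30.716  39.290   2.700  1.00  0.00           C
ATOM     21  CA  ALA A 321     -10.626  48.746   0.000  1.00  0.00           C
ATOM     22  CA  ARG A 322     -11.190  49.242   0.300  1.00  0.00           C
ATOM     23  CA  ASN A 323     -11.609  48.619   0.600  1.00  0.00           C
ATOM     24  CA  ASP A 324     -10.937  48.283   0.900  1.00  0.00           C
ATOM     25  CA  CYS A 325     -10.691  48.993   1.200  1.00  0.00           C
ATOM     26  CA  GLN A 326     -11.427  49.146   1.500  1.00  0.00           C
ATOM     27  CA  GLU A 327     -11.483  48.396   1.800  1.00  0.00           C
ATOM     28  CA  GLY A 328     -10.733  48.437   2.100  1.00  0.00           C
ATOM     29  CA  HIS A 329     -10.870  49.176   2.400  1.00  0.00           C
ATOM     30  CA  ILE A 330     -11.585  48.945   2.700  1.00  0.00           C
ATOM     31  CA  LEU A 331     -44.548  21.694   0.000  1.00  0.00           C
ATOM     32  CA  LYS A 332     -45.113  22.190   0.300  1.00  0.00           C
ATOM     33  CA  MET A 333     -45.532  21.566   0.600  1.00  0.00           C
ATOM     34  CA  PHE A 334     -44.859  21.231   0.900  1.00  0.00           C
ATOM     35  CA  PRO A 335     -44.614  21.941   1.200  1.00  0.00           C
ATOM     36  CA  SER A 336     -45.349  22.093   1.500  1.00  0.00           C
ATOM     37  CA  THR A 337     -45.406  21.344   1.800  1.00  0.00           C
ATOM     38  CA  TRP A 338     -44.655  21.385   2.100  1.00  0.00           C
ATOM     39  CA  TYR A 339     -44.793  22.124   2.400  1.00  0.00           C
ATOM     40  CA  VAL A 340     -45.507  21.893   2.700  1.00  0.00           C
ATOM     41  CA  ALA A 341     -44.548 -21.694   0.000  1.00  0.00           C
ATOM     42  CA  ARG A 342     -45.113 -21.198   0.300  1.00  0.00           C
ATOM     43  CA  ASN A 343     -45.532 -21.822   0.600  1.00  0.00           C
ATOM     44  CA  ASP A 344     -44.859 -22.157   0.900  1.00  0.00           C
ATOM     45  CA  CYS A 345     -44.614 -21.447   1.200  1.00  0.00           C
ATOM     46  CA  GLN A 346     -45.349 -21.295   1.500  1.00  0.00           C
ATOM     47  CA  GLU A 347     -45.406 -22.044   1.800  1.00  0.00           C
ATOM     48  CA  GLY A 348     -44.655 -22.003   2.100  1.00  0.00           C
ATOM     49  CA  HIS A 349     -44.793 -21.265   2.400  1.00  0.00           C
ATOM     50  CA  ILE A 350     -45.507 -21.496   2.700  1.00  0.00           C
ATOM     51  CA  LEU A 351     -10.626 -48.746   0.000  1.00  0.00           C
ATOM     52  CA  LYS A 352     -11.190 -48.251   0.300  1.00  0.00           C
ATOM     53  CA  MET A 353     -11.609 -48.874   0.600  1.00  0.00           C
ATOM     54  CA  PHE A 354     -10.937 -49.209   0.900  1.00  0.00           C
ATOM     55  CA  PRO A 355     -10.691 -48.499   1.200  1.00  0.00           C
ATOM     56  CA  SER A 356     -11.427 -48.347   1.500  1.00  0.00           C
ATOM     57  CA  THR A 357     -11.483 -49.096   1.800  1.00  0.00           C
ATOM     58  CA  TRP A 358     -10.733 -49.055   2.100  1.00  0.00           C
ATOM     59  CA  TYR A 359     -10.870 -48.317   2.400  1.00  0.00           C
ATOM     60  CA  VAL A 360     -11.585 -48.548   2.700  1.00  0.00           C
ATOM     61  CA  ASP A 364      31.363 -39.554   0.900  1.00  0.00           C
ATOM     62  CA  CYS A 365      31.609 -38.845   1.200  1.00  0.00           C
ATOM     63  CA  GLN A 366      30.873 -38.692   1.500  1.00  0.00           C
ATOM     64  CA  GLU A 367      30.817 -39.442   1.800  1.00  0.00           C
ATOM     65  CA  GLY A 368      31.568 -39.401   2.100  1.00  0.00           C
ATOM     66  CA  HIS A 369      31.430 -38.662   2.400  1.00  0.00           C
ATOM     67  CA  ILE A 370      30.716 -38.893   2.700  1.00  0.00           C
END
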