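rosiglitazone
 OpenBabel10022608383D

 44 46  0  0  1  0  0  0  0  0999 V2000
    5.7184   -0.7188    0.5835 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.3930   -1.0803    0.1043 N   0  0  0  0  0  0  0  0  0  0  0  0
    3.2428   -0.6758    0.9287 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.3827   -1.8861    1.3249 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.0732   -2.7265    2.2700 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.3823   -3.8392    2.6817 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.3461   -4.4462    1.9721 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6826   -5.5618    2.4908 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.0420   -6.0969    3.7319 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.2594   -7.2557    4.3142 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.7217   -8.6688    3.9487 C   0  0  3  0  0  0  0  0  0  0  0  0
    2.4185   -9.0677    4.4847 S   0  0  0  0  0  0  0  0  0  0  0  0
    2.9423   -9.4297    2.8630 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.0978   -9.6883    2.5635 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.8997   -9.3846    2.0032 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.7001   -8.9304    2.4590 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2760   -8.7727    1.7355 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.1115   -5.5125    4.4244 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.7789   -4.3985    3.8986 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.1993   -1.2258   -1.2690 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.2377   -1.6459   -2.1056 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.0438   -1.7571   -3.4854 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.8032   -1.4535   -4.0174 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.8117   -1.0697   -3.1362 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.9820   -0.9651   -1.7963 N   0  0  0  0  0  0  0  0  0  0  0  0
    5.7077   -0.4452    1.6440 H   0  0  0  0  0  0  0  0  0  0  0  0
    6.1192    0.1383    0.0297 H   0  0  0  0  0  0  0  0  0  0  0  0
    6.4087   -1.5637    0.4918 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.6252    0.0658    0.4071 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.5892   -0.1830    1.8455 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.1281   -2.4451    0.4204 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.4674   -1.5154    1.8035 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.0259   -4.0809    1.0026 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1342   -5.9941    1.9155 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7859   -7.1382    3.9970 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.2339   -7.1491    5.4053 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.0523   -9.4005    4.4152 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.0477   -9.5577    1.0224 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.4257   -5.9067    5.3885 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.6015   -3.9526    4.4545 H   0  0  0  0  0  0  0  0  0  0  0  0
    6.2089   -1.9069   -1.7036 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.8581   -2.0799   -4.1249 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.6157   -1.5198   -5.0832 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.8170   -0.8270   -3.4953 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1 26  1  0  0  0  0
  1 27  1  0  0  0  0
  1 28  1  0  0  0  0
  2  3  1  0  0  0  0
  2 20  1  0  0  0  0
  3  4  1  0  0  0  0
  3 29  1  0  0  0  0
  3 30  1  0  0  0  0
  4  5  1  0  0  0  0
  4 31  1  0  0  0  0
  4 32  1  0  0  0  0
  5  6  1  0  0  0  0
  6  7  1  0  0  0  0
  6 19  2  0  0  0  0
  7  8  2  0  0  0  0
  7 33  1  0  0  0  0
  8  9  1  0  0  0  0
  8 34  1  0  0  0  0
  9 10  1  0  0  0  0
  9 18  2  0  0  0  0
 10 11  1  0  0  0  0
 10 35  1  0  0  0  0
 10 36  1  0  0  0  0
 11 12  1  0  0  0  0
 11 16  1  0  0  0  0
 11 37  1  0  0  0  0
 12 13  1  0  0  0  0
 13 14  2  0  0  0  0
 13 15  1  0  0  0  0
 15 16  1  0  0  0  0
 15 38  1  0  0  0  0
 16 17  2  0  0  0  0
 18 19  1  0  0  0  0
 18 39  1  0  0  0  0
 19 40  1  0  0  0  0
 20 21  1  0  0  0  0
 20 25  2  0  0  0  0
 21 22  2  0  0  0  0
 21 41  1  0  0  0  0
 22 23  1  0  0  0  0
 22 42  1  0  0  0  0
 23 24  2  0  0  0  0
 23 43  1  0  0  0  0
 24 25  1  0  0  0  0
 24 44  1  0  0  0  0
M  END
$$$$
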