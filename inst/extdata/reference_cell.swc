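# SWC written by rgcsim
1 1 0.000000 0.000000 0.000000 8.250000 -1
2 3 1.123336 -12.799834 38.454074 0.950000 1
3 3 7.536666 9.830246 30.813072 0.950000 1
4 3 -12.829859 -2.269421 28.098786 0.950000 1
5 3 10.031538 -6.381243 22.789121 0.950000 1
6 3 -4.276901 7.288778 74.476193 0.589000 2
7 3 -8.183621 -30.719815 70.408875 0.589000 2
8 3 22.674365 15.358509 54.316142 0.589000 3
9 3 -10.960080 17.465434 57.881295 0.589000 3
10 3 -4.170917 -20.773078 53.858299 0.589000 4
11 3 -6.079517 19.251734 54.712914 0.589000 4
12 3 -6.346079 -15.872407 43.756673 0.589000 5
13 3 30.408960 -10.861163 44.538996 0.589000 5
14 3 -12.827747 19.451477 89.091618 0.365180 6
15 3 -7.822407 -20.071645 100.092011 0.365180 6
16 3 6.167534 -18.624645 86.888025 0.365180 7
17 3 -41.436677 -29.344696 98.069481 0.365180 7
18 3 45.660048 -7.515315 79.844109 0.365180 8
19 3 21.420241 42.480101 74.570050 0.365180 8
20 3 -25.100363 0.520648 73.485713 0.365180 9
21 3 -2.758061 18.569004 63.427396 0.365180 9
22 3 -21.788643 -8.515123 67.487977 0.365180 10
23 3 1.847077 -47.523665 70.351939 0.365180 10
24 3 4.322337 37.404356 66.626858 0.365180 11
25 3 -27.908788 12.287601 67.055072 0.365180 11
26 3 17.924523 -27.086041 57.364846 0.365180 12
27 3 -20.218845 17.275857 61.017738 0.365180 12
28 3 16.446485 -49.680401 63.212562 0.365180 13
29 3 65.385178 7.521357 61.362921 0.365180 13
30 3 -32.884772 24.738444 97.381823 0.226412 14
31 3 13.791327 -21.947299 107.512013 0.226412 14
32 3 -3.648180 4.216987 108.704371 0.226412 15
33 3 -32.793748 -39.410856 110.363995 0.226412 15
34 3 50.412566 -22.290256 100.273333 0.226412 16
35 3 -14.926685 4.177588 95.530429 0.226412 16
36 3 -41.392883 -38.322047 100.361987 0.226412 17
37 3 -14.177335 0.704750 107.517459 0.226412 17
38 3 23.665962 -9.553722 84.498414 0.226412 18
39 3 75.098917 -29.858367 86.823427 0.226412 18
40 3 17.369941 64.744133 78.354583 0.226412 19
41 3 2.907375 13.061305 79.639904 0.226412 19
42 3 1.162792 7.718291 76.880648 0.226412 20
43 3 -56.851033 16.814568 77.184544 0.226412 20
44 3 8.144315 -10.838283 66.022894 0.226412 21
45 3 4.992962 37.609200 64.701428 0.226412 21
46 3 -49.557664 -21.675380 68.756258 0.226412 22
47 3 -1.139042 -14.881616 67.933614 0.226412 22
48 3 -11.496843 -24.754631 70.351939 0.226412 23
49 3 -5.050684 -79.645339 69.674394 0.226412 23
50 3 29.597625 55.358737 65.347286 0.226412 24
51 3 -33.151919 42.074701 64.286448 0.226412 24
52 3 -4.664340 -15.020931 64.087297 0.226412 25
53 3 -26.464639 51.888653 62.947891 0.226412 25
54 3 2.927630 -42.304034 54.701202 0.226412 26
55 3 53.971526 -25.242934 52.100267 0.226412 26
56 3 -43.665973 36.649042 55.931112 0.226412 27
57 3 -15.223411 -18.528961 54.190614 0.226412 27
58 3 35.422982 -22.120655 56.161861 0.226412 28
59 3 -11.000171 -55.995813 56.653966 0.226412 28
60 3 101.100842 -12.713710 50.880402 0.226412 29
61 3 54.830302 40.056916 51.846391 0.226412 29
62 2 -11.919711 -26.132900 -8.659794 0.500000 1
63 2 -3.165268 -22.418818 -11.752577 0.500000 62
64 2 -29.860843 -12.963793 -21.649485 0.200000 63
65 2 -3.475594 -62.577488 -42.680412 0.200000 64
66 2 1237.020799 4738.361671 -2024.536082 0.500000 65
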