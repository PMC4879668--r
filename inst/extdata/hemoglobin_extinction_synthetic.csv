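"wavelength_nm","eps_oxy","eps_deoxy"
400,140000,170000
402,183096.8,180930
404,236901.2,192883.4
406,3e+05,206312.1
408,368101.9,221780.1
410,434407.8,240000
412,489769.3,261745.6
414,524000,287395.6
416,529395.6,317199.1
418,506210.4,351361.2
420,460000,390000
422,398599.2,432581.7
424,329570,475891.2
426,260000,514768
428,196669.8,542760.1
430,146195.1,553000
432,110000,540353.1
434,86006.8,504806.4
436,70809.7,450000
438,62000,382840.8
440,58031,313579.8
442,57248.6,250000
444,58409.3,196353.2
446,60476.6,154493.3
448,62353.1,123973.3
450,62816,103292
452,60979.2,90506.7
454,57395.7,82765.8
456,52970,77990.4
458,48473.3,74767.7
460,44480,72000
462,41291.2,68928
464,38753.4,65546.5
466,36662.8,62011.7
468,34858.4,58459
470,33209,55000
472,31630.7,51707.8
474,30146.7,48578.4
476,28797.3,45593.6
478,27615.7,42738.2
480,26629,40000
482,25846.2,37371.4
484,25216.4,34854.4
486,24680.9,32452.4
488,24186.3,30167.4
490,23684,28000
492,23140.6,25970.7
494,22570.4,24169.6
496,21998,22678.3
498,21445.2,21557.9
500,20932,20862
502,20480.1,20615.4
504,20124,20720.4
506,19900.2,21061.6
508,19845.6,21527.5
510,20000,22000
512,20384.5,22383.4
514,20921.1,22707.4
516,21500,23037.4
518,22079,23443.3
520,22939.1,24000
522,24500,24777.2
524,27170.4,25798.1
526,30858,27077.6
528,35188.2,28636.2
530,39500,30500
532,43016.8,32684.6
534,45730.5,35137.5
536,48000,37765.4
538,50166.3,40441.1
540,52035.3,43000
542,53236,45280.9
544,53374.3,47264.7
546,52052.7,48986.9
548,49000,50500
550,44448.4,51830.4
552,39730.4,52849
554,36000,53381.5
556,33806.5,53269.1
558,32809.6,52608.2
560,32613,51739.7
562,32981.6,51000
564,34028.1,50517.6
566,36000,49665.9
568,39118.1,47687.1
570,43129.3,44000
572,47500,38628.1
574,51438.4,32754
576,53883.1,27400
578,53716.3,23057.4
580,50343.8,19761.5
582,44000,17433.6
584,35677.4,16000
586,27000,15338.1
588,19325.6,15020.5
590,13500,14600
592,9501.4,13777.1
594,6842.5,12678
596,5100,11504.8
598,3965.8,10410.9
600,3200,9500
602,2657.3,8816.9
604,2257.3,8308.5
606,1950.6,7915.8
608,1705.3,7592.4
610,1500,7300
612,1322,7012.3
614,1169.2,6731.5
616,1040.7,6465.1
618,934.9,6219.4
620,850,6000
622,783.6,5808.7
624,730.6,5637.3
626,686.3,5475.9
628,647,5315.7
630,610,5149
632,573.5,4971.7
634,538.2,4790.5
636,505.4,4613.5
638,475.7,4448
640,450,4300
642,428.3,4172.7
644,410.1,4060.7
646,394.4,3956.9
648,380.5,3855.2
650,368,3750
652,356.3,3638
654,345.6,3522.5
656,335.9,3408.4
658,327.3,3299.7
660,320,3200
662,314,3111.2
664,309,3030.4
666,305.1,2953.9
668,302,2878.1
670,299.5,2800
672,297.5,2717.9
674,295.9,2634
676,294.5,2551.4
678,293.2,2472.6
680,292,2400
682,290.7,2334.8
684,289.3,2274.8
686,288,2217.3
688,287,2159.8
690,286.2,2100
692,285.8,2036.8
694,285.8,1972.3
696,286.5,1908.8
698,287.8,1848.8
700,290,1794
702,293.1,1745.8
704,297,1703.4
706,301.7,1665.6
708,307.1,1631.4
710,313.1,1600
712,319.7,1570.4
714,326.8,1542.2
716,334.3,1514.6
718,342.1,1487.4
720,350,1460
722,358,1432.4
724,366.2,1406
726,374.5,1382.4
728,383.1,1363.2
730,392.1,1350
732,401.6,1343.5
734,411.6,1342.4
736,422.2,1344.4
738,433.6,1347.6
740,446,1350
742,459.4,1350.5
744,473.5,1352.1
746,488.3,1358.9
748,503.2,1375
750,518,1405
752,532.3,1451.1
754,546.2,1504.1
756,559.7,1550
758,573,1575.7
760,586,1576.2
762,599,1550
764,611.9,1498.7
766,624.7,1432.7
768,637.4,1363.2
770,650,1300
772,662.4,1248.9
774,674.6,1207.2
776,686.7,1170.8
778,698.5,1136.1
780,710,1100
782,721.3,1060.4
784,732.3,1018.8
786,743.1,977.1
788,753.8,937
790,764.2,900
792,774.6,866.9
794,784.9,837.2
796,795.3,810.1
798,805.6,784.9
800,816,761
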