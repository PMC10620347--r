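a
ability
about
above
absent
accept
achieve
activity
adapt
adaptation
affirm
after
again
against
aide
all
alone
always
am
an
and
animal
anxiety
any
anything
applicable
are
around
arrange
art
as
ask
asks
at
attempt
avoid
away
barely
bath
be
because
bed
been
before
being
belief
belong
below
best
better
between
big
biking
book
books
both
brave
breakdown
breakfast
breaks
bring
brother
brush
build
bus
but
buy
by
calendar
call
calm
can
cannot
capable
car
catch
celebrate
chair
challenge
character
chart
checklist
child
choice
choices
choose
chore
church
class
clean
close
clothes
club
coach
color
come
comfort
community
competence
computer
concern
confidence
confident
cook
corner
correct
courage
craft
cue
dad
daily
dance
dancing
daughter
day
decide
demonstrate
depends
described
desk
did
difficulty
dinner
dinosaur
do
doctor
does
doing
don
door
down
draw
drawing
dress
drill
drink
drive
drum
drums
during
each
early
easy
eat
effort
emotion
encourage
enjoy
environment
equipment
esteem
evening
event
exercise
explore
family
fast
favorite
fear
feedback
feel
feeling
few
find
finish
first
focus
food
foot
for
friend
from
fun
further
game
games
get
give
gives
go
goal
goes
good
great
group
grow
guide
had
happy
hard
hardly
has
have
having
he
headphones
help
helped
helper
helping
her
here
hers
herself
him
himself
his
hobby
holiday
home
homework
hour
house
how
i
idea
identity
if
improve
in
independent
inside
inspire
instruction
interest
into
is
issue
it
its
itself
join
journal
just
keep
kid
know
lack
last
late
learn
leave
lego
lesson
let
lets
level
lighting
like
likes
limited
listen
little
love
loves
lunch
make
makes
man
master
maybe
me
menu
method
milestone
minute
missing
model
modify
mom
month
mood
more
morning
most
motivate
mouse
movie
music
my
myself
need
needed
needs
never
new
next
nice
night
no
nobody
noise
noises
none
nor
not
nothing
now
of
off
often
old
on
once
only
open
option
or
other
our
ours
ourselves
out
outing
outside
over
own
painting
parent
park
party
passion
peer
perhaps
phone
pick
picture
pictures
plan
play
played
playing
plays
positive
practice
praise
prefer
pride
problem
progress
project
prompt
proud
put
puts
question
quiet
quit
rail
ramp
rarely
read
reading
really
reassure
reflect
refuse
rehearse
reminder
repeat
respect
rest
reward
rewards
ride
room
routine
run
s
same
say
scaffold
schedule
school
seating
secure
see
seldom
select
sequence
session
set
setup
share
she
shoes
shop
should
show
shows
sibling
sing
singing
sister
sit
sits
skill
skills
sleep
slow
snack
so
some
sometimes
son
song
songs
space
speak
special
sport
stand
start
stay
step
steps
stop
store
strategies
strategy
strength
struggle
success
such
support
swim
swimming
t
table
tablet
take
takes
talk
task
teach
teacher
team
technique
tell
tells
than
that
the
their
theirs
them
theme
themselves
then
therapist
therapy
there
these
they
think
this
those
through
time
timer
to
together
too
tooth
toy
train
transport
tries
trip
trust
try
turn
tutor
unable
unclear
undecided
under
unknown
unsure
until
up
use
uses
using
usually
value
varies
very
visit
visual
wait
waiting
wake
walk
walks
want
wants
was
wash
watch
water
we
wear
week
weekend
well
were
what
wheelchair
when
where
which
while
who
whom
why
will
wish
with
without
woman
wonder
work
works
worry
worth
would
write
yard
year
you
your
yours
yourself
yourselves
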